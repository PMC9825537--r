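# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (double loops, transitive closure by matrix powers,
# textbook DP) and share no code with the package internals they check.

# cached template chains so each test file does not regenerate them
tpl30 <- function(seed = 1) {
  key <- paste0("tpl", seed)
  env <- testthat::teardown_env()
  if (is.null(attr(env, key))) attr(env, key) <- make_template_chain(30, seed = seed)
  attr(env, key)
}

# brute-force contact scan: O(n^2) double loop over residues and atoms
brute_contacts <- function(chainA, chainB, cb_cut = 12, at_cut = 5) {
  cb <- NULL
  posA <- chainA$rep$seq_pos; posB <- chainB$rep$seq_pos
  for (i in seq_along(posA)) for (j in seq_along(posB)) {
    d <- sqrt(sum((chainA$rep$xyz[i, ] - chainB$rep$xyz[j, ])^2))
    if (d <= cb_cut) cb <- rbind(cb, data.frame(pos_i = posA[i], pos_j = posB[j], d = d))
  }
  at <- NULL
  aa <- chainA$atoms; ab <- chainB$atoms
  for (i in seq_len(nrow(aa))) for (j in seq_len(nrow(ab))) {
    d <- sqrt((aa$x[i] - ab$x[j])^2 + (aa$y[i] - ab$y[j])^2 + (aa$z[i] - ab$z[j])^2)
    if (d <= at_cut) at <- rbind(at, data.frame(pos_i = aa$seq_pos[i], pos_j = ab$seq_pos[j]))
  }
  list(cb = cb, at = if (is.null(at)) at else unique(at))
}

# single-linkage closure by boolean matrix powers (independent of union-find)
closure_membership <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      label <- label + 1L
      comp[reach[i, ]] <- label
    }
  }
  comp
}

# textbook Needleman-Wunsch with affine-ish linear scoring matching the
# package's parameters (match 1, mismatch -1, gap open 10, extend 0.5);
# linear-gap approximation with per-gap-column cost gopen applied on opening
nw_align_oracle <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 10, gap_ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (av[i - 1] == bv[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  from <- integer(0); to <- integer(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      from <- c(i - 1, from); to <- c(j - 1, to)
      s <- if (av[i - 2 + 1] == bv[j - 2 + 1]) match else mismatch
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      up <- c(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      state <- if (which.max(up) == 1) 1 else 2
      i <- i - 1
    } else {
      left <- c(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      state <- if (which.max(left) == 1) 1 else 3
      j <- j - 1
    }
  }
  stats::setNames(as.integer(to), as.integer(from))
}

# apply one random rigid-body transform to every chain of an assembly and
# recompute its interfaces
rigid_move <- function(assembly, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  tr <- stats::rnorm(3, sd = 20)
  assembly$chains <- lapply(assembly$chains, function(ch)
    apply_operator(ch, q, tr, id_suffix = ""))
  names(assembly$chains) <- vapply(assembly$chains, function(ch) ch$chain_id, "")
  assembly$interfaces <- find_interfaces(assembly)
  assembly$iface_clusters <- NULL
  assembly
}

# bare chain built from explicit representative/atom coordinates
point_chain <- function(chain_id, ca_xyz, extra_atoms = NULL, seq = NULL) {
  n <- nrow(ca_xyz)
  atoms <- data.frame(seq_pos = seq_len(n), atom = "CA",
                      x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(extra_atoms)) atoms <- rbind(atoms, extra_atoms)
  new_chain(chain_id, seq %||% paste(rep("A", n), collapse = ""), atoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chain_xyz_ <- function(ch) as.matrix(ch$atoms[, c("x", "y", "z")])
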