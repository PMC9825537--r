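# Entity assignment, stoichiometry strings, and point-group detection.
#
# The detector tests candidate rotations obtained by superposing every chain
# that is interchangeable with a reference chain onto that reference, about
# the assembly centroid (orthogonal Procrustes, no translation). A candidate
# is kept when it maps the whole assembly onto itself within an RMSD
# tolerance. The validated rotation set is then classified as Cn (all
# non-identity axes colinear), Dn (an order-n principal axis plus n
# perpendicular 2-folds), polyhedral (group order 12/24/60 with multiple
# high-order axes), C1, or unknown.
#
# "Strict" mode treats chains as interchangeable when they share an entity
# (sequence) key; "pseudo" mode when they share a chain Pfam architecture, so
# an A3B3 hexamer of two homologous proteins can be recognized as D3 rather
# than C3.

#' Assign entity keys to chains by sequence identity
#'
#' Chains with a user-supplied entity key keep it. The remaining chains are
#' grouped by single linkage over global pairwise sequence identity at
#' `identity_threshold` and each group gets a synthetic key (`ENT1`, `ENT2`,
#' ... in order of first chain).
#'
#' @param chains list of `qc_chain`.
#' @param identity_threshold fraction in (0,1]; default 0.95.
#' @return named character vector chain_id -> entity_key.
#' @export
assign_entities <- function(chains, identity_threshold = 0.95) {
  ids <- vapply(chains, `[[`, "", "chain_id")
  keys <- vapply(chains, `[[`, "", "entity_key")
  names(keys) <- ids
  todo <- which(is.na(keys))
  if (length(todo) > 0) {
    seqs <- vapply(chains[todo], `[[`, "", "sequence")
    n <- length(todo)
    pairs <- NULL
    if (n >= 2) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (sequence_identity(seqs[i], seqs[j]) >= identity_threshold * 100)
          pairs <- rbind(pairs, c(i, j))
      }
    }
    memb <- single_linkage(n, pairs %||% matrix(integer(0), 0, 2))
    keys[todo] <- sprintf("ENT%d", memb)
  }
  keys
}

#' Global pairwise sequence identity (percent)
#'
#' Needleman-Wunsch global alignment (match 1, mismatch -1, gap open 10,
#' extend 0.5) via Biostrings; identity = identical columns over alignment
#' length, in [0, 100].
#'
#' @param seq_a,seq_b one-letter amino-acid strings.
#' @return numeric percent identity.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (identical(seq_a, seq_b)) return(100)
  pa <- align_global(seq_a, seq_b)
  Biostrings::pid(pa, type = "PID1")
}

# grouping key per chain for a symmetry/stoichiometry mode
chain_group_keys <- function(assembly, grouping = c("by_entity", "by_arch"),
                             entities = NULL, archs = NULL) {
  grouping <- match.arg(grouping)
  ids <- names(assembly$chains)
  if (grouping == "by_entity") {
    keys <- entities %||% assign_entities(assembly$chains)
  } else {
    keys <- archs %||% stats::setNames(
      vapply(assembly$chains, function(ch) ch$pfam_arch %||% "(NA)", ""), ids)
  }
  keys[ids]
}

#' Stoichiometry string of an assembly
#'
#' Groups chains by entity (or by chain architecture) and assigns letters A,
#' B, C, ... in descending copy count (ties broken by lexicographic group
#' key), suffixing the copy count when > 1: a homodimer is "A2", a 2+1+1
#' hetero-tetramer "A2BC", and the same tetramer grouped by a shared
#' architecture "A4".
#'
#' @param assembly a `qc_assembly`.
#' @param grouping "by_entity" or "by_arch".
#' @param entities,archs optional precomputed named key vectors.
#' @return stoichiometry string.
#' @export
stoichiometry <- function(assembly, grouping = "by_entity",
                          entities = NULL, archs = NULL) {
  keys <- chain_group_keys(assembly, grouping, entities, archs)
  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  counts <- as.integer(tab)[ord]
  letters_out <- c(LETTERS, paste0(rep(LETTERS, each = 26), rep(LETTERS, 26)))
  paste0(vapply(seq_along(counts), function(k) {
    paste0(letters_out[k], if (counts[k] > 1) counts[k] else "")
  }, ""), collapse = "")
}

# align chain positions for superposition: identical sequences -> identity;
# otherwise aligned columns of a global alignment (both chains must keep >=3)
aligned_rep_coords <- function(cha, chb) {
  if (identical(cha$sequence, chb$sequence) && chain_length(cha) == chain_length(chb))
    return(list(a = cha$rep$xyz, b = chb$rep$xyz))
  mp <- pairwise_position_map(cha$sequence, chb$sequence)
  ia <- as.integer(names(mp$map)); ib <- unname(mp$map)
  ka <- match(ia, cha$rep$seq_pos); kb <- match(ib, chb$rep$seq_pos)
  ok <- !is.na(ka) & !is.na(kb)
  list(a = cha$rep$xyz[ka[ok], , drop = FALSE], b = chb$rep$xyz[kb[ok], , drop = FALSE])
}

#' Detect the point-group symmetry of an assembly
#'
#' @param assembly a `qc_assembly`.
#' @param mode "strict_entity" (chains interchangeable within an entity) or
#'   "pseudo_by_arch" (interchangeable within a chain Pfam architecture).
#' @param rmsd_tol superposition tolerance in Angstroms (default 3.0).
#' @param angle_tol rotation-angle tolerance in degrees (default 8).
#' @param axis_tol axis colinearity/perpendicularity tolerance in degrees
#'   (default 10).
#' @param entities,archs optional precomputed named key vectors.
#' @return object of class `qc_symmetry`: list(label, axis_order, mode,
#'   mean_rmsd).
#' @export
detect_point_group <- function(assembly, mode = c("strict_entity", "pseudo_by_arch"),
                               rmsd_tol = 3.0, angle_tol = 8, axis_tol = 10,
                               entities = NULL, archs = NULL) {
  mode <- match.arg(mode)
  grouping <- if (mode == "strict_entity") "by_entity" else "by_arch"
  keys <- chain_group_keys(assembly, grouping, entities, archs)
  chains <- assembly$chains
  ids <- names(chains)
  n_chain <- length(ids)
  if (n_chain == 1)
    return(structure(list(label = "C1", axis_order = 1L, mode = mode, mean_rmsd = 0),
                     class = "qc_symmetry"))
  for (ch in chains) if (chain_length(ch) < 3)
    qc_stop("qc_symmetry_error", "chain %s has <3 aligned positions", ch$chain_id)

  centroid <- colMeans(do.call(rbind, lapply(chains, function(ch) ch$rep$xyz)))
  centered <- lapply(chains, function(ch) sweep(ch$rep$xyz, 2, centroid))

  # reference chain: longest, ties by lexicographic chain id
  lens <- vapply(chains, chain_length, integer(1))
  ref <- ids[order(-lens, ids)][1]
  peers <- ids[keys == keys[ref]]

  # candidate rotations: orthogonal Procrustes ref -> peer about the centroid
  cand <- list()
  for (p in peers) {
    co <- aligned_rep_coords(chains[[ref]], chains[[p]])
    A <- sweep(co$a, 2, centroid); B <- sweep(co$b, 2, centroid)
    fit <- kabsch(A, B, center = FALSE)
    if (fit$rmsd <= rmsd_tol) cand[[p]] <- fit$rot
  }

  # validate: rotation must map every chain onto a same-group chain
  ops <- list(); rmsds <- numeric(0)
  for (p in names(cand)) {
    R <- cand[[p]]
    ok <- TRUE; worst <- 0
    for (cid in ids) {
      moved <- centered[[cid]] %*% t(R)
      targets <- ids[keys == keys[cid]]
      best <- Inf
      for (tid in targets) {
        if (chain_length(chains[[tid]]) != nrow(moved)) next
        r <- sqrt(mean(rowSums((moved - centered[[tid]])^2)))
        if (r < best) best <- r
      }
      if (best > rmsd_tol) { ok <- FALSE; break }
      worst <- max(worst, best)
    }
    if (ok) { ops[[p]] <- R; rmsds <- c(rmsds, worst) }
  }

  order_g <- length(ops)
  mean_rmsd <- if (length(rmsds)) mean(rmsds) else NA_real_
  res <- function(label, axis_order)
    structure(list(label = label, axis_order = as.integer(axis_order),
                   mode = mode, mean_rmsd = mean_rmsd),
              class = "qc_symmetry")
  if (order_g <= 1) return(res("C1", 1))

  aa <- lapply(ops, rotation_angle_axis)
  ang <- vapply(aa, `[[`, numeric(1), "angle")
  nonid <- which(ang > angle_tol / 2)
  axes <- lapply(aa[nonid], `[[`, "axis")
  angs <- ang[nonid]

  colinear_all <- function(axlist) {
    if (length(axlist) <= 1) return(TRUE)
    all(vapply(axlist[-1], function(u) axis_angle_deg(axlist[[1]], u) <= axis_tol,
               logical(1)))
  }

  if (colinear_all(axes)) {
    n <- order_g
    # reported angles lie in [0,180]: expected multiset is min(k*360/n, 360-k*360/n)
    expected <- sort(vapply(seq_len(n - 1), function(k)
      min(k * 360 / n, 360 - k * 360 / n), numeric(1)))
    if (length(angs) == n - 1 && all(abs(sort(angs) - expected) <= angle_tol))
      return(res(sprintf("C%d", n), n))
    return(res("unknown", 0))
  }

  # non-colinear axes: dihedral or polyhedral
  twofold <- abs(angs - 180) <= angle_tol
  if (order_g %% 2 == 0) {
    n <- order_g / 2
    if (n == 2 && order_g == 4 && all(twofold)) {
      # D2: three mutually perpendicular 2-folds
      perp <- TRUE
      for (i in seq_along(axes)) for (j in seq_along(axes)) {
        if (j <= i) next
        d <- axis_angle_deg(axes[[i]], axes[[j]])
        if (abs(d - 90) > axis_tol && d > axis_tol) perp <- FALSE
      }
      if (perp) return(res("D2", 2))
    } else if (n >= 3) {
      # principal axis: the axis shared by the non-2-fold rotations (or, for
      # n even, the axis with the most rotations about it)
      ax_principal <- NULL
      npf <- which(!twofold)
      if (length(npf) > 0) ax_principal <- axes[[npf[1]]]
      else ax_principal <- axes[[1]]
      about <- vapply(axes, function(u) axis_angle_deg(u, ax_principal) <= axis_tol,
                      logical(1))
      n_about <- sum(about) + 1L  # + identity
      perp2 <- vapply(seq_along(axes), function(k) {
        twofold[k] && abs(axis_angle_deg(axes[[k]], ax_principal) - 90) <= axis_tol
      }, logical(1))
      if (n_about == n && sum(perp2) == n)
        return(res(sprintf("D%d", n), n))
    }
  }
  if (order_g %in% c(12, 24, 60)) return(res("polyhedral", order_g))
  res("unknown", 0)
}

#' Annotate an assembly with stoichiometry, symmetry and architecture
#'
#' Fills the `stoichiometry` (by entity), `symmetry` (strict and, for
#' same-architecture heteromers, pseudo), and `pfam_assembly_arch` fields.
#' The pseudo-symmetry label is the one used for the clustering gate when the
#' chains share one architecture; the strict label is retained in
#' `symmetry_strict`.
#'
#' @param assembly a `qc_assembly`.
#' @param archs named chain_id -> chain-architecture vector; default "(NA)"
#'   unless chains carry a `pfam_arch`.
#' @param entities named chain_id -> entity vector; default from
#'   [assign_entities()].
#' @param ... tolerances passed to [detect_point_group()].
#' @return the assembly with fields filled.
#' @export
annotate_assembly <- function(assembly, archs = NULL, entities = NULL, ...) {
  ids <- names(assembly$chains)
  entities <- entities %||% assign_entities(assembly$chains)
  if (is.null(archs))
    archs <- stats::setNames(
      vapply(assembly$chains, function(ch) ch$pfam_arch %||% "(NA)", ""), ids)
  assembly$entities <- entities[ids]
  assembly$chain_archs <- archs[ids]
  assembly$stoichiometry <- stoichiometry(assembly, "by_entity", entities = entities)
  assembly$stoich_by_arch <- stoichiometry(assembly, "by_arch", archs = archs)
  assembly$pfam_assembly_arch <- assembly_architecture_from_chains(archs[ids])
  strict <- detect_point_group(assembly, "strict_entity", entities = entities,
                               archs = archs, ...)
  assembly$symmetry_strict <- strict$label
  hetero_same_arch <- length(unique(entities[ids])) > 1 &&
    length(unique(archs[ids])) < length(unique(entities[ids]))
  if (hetero_same_arch) {
    pseudo <- detect_point_group(assembly, "pseudo_by_arch", entities = entities,
                                 archs = archs, ...)
    assembly$symmetry <- pseudo$label
    assembly$symmetry_pseudo <- pseudo$label
  } else {
    assembly$symmetry <- strict$label
    assembly$symmetry_pseudo <- NA_character_
  }
  assembly
}
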