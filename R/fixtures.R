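# Synthetic assembly fixtures.
#
# The template chain is a compact "ball" of residues on a Fibonacci sphere
# plus a short "arm" pointing at the next subunit position, so ring
# neighbours contact through arm-to-ball interfaces while non-neighbours stay
# beyond the interface criteria. Cyclic (Cn) assemblies place n copies at
# exact 360/n-degree rotations about z; dihedral (Dn) assemblies stack two Cn
# rings related by an exact perpendicular 2-fold. Generation asserts the
# intended contact graph, so downstream symmetry and interface tests run on
# exact geometry.

ARM_LEN <- 6L          # residues in the contact arm
BALL_RADIUS <- 4       # A, radius of the residue sphere
NEIGHBOR_DIST <- 17    # A, adjacent subunit center distance
RING_HALF_GAP <- 6.6   # A, half the inter-ring center distance in Dn

#' Deterministic pseudo-protein template chain
#'
#' `len - 6` residues on a Fibonacci sphere of radius 4 A around the local
#' origin plus a 6-residue arm along +x reaching the neighbour position at
#' `NEIGHBOR_DIST`. Each residue carries CA, CB and one side-chain proxy atom
#' (CG). The sequence is drawn from the 20 standard residues under the seed.
#'
#' @param len total residues (>= 10).
#' @param seed RNG seed; same seed, same chain.
#' @param chain_id,entity_key identifiers for the returned chain.
#' @return a `qc_chain`.
#' @export
make_template_chain <- function(len, seed = 1, chain_id = "A",
                                entity_key = NA_character_) {
  if (len < 10) qc_stop("qc_fixture_error", "template length must be >= 10")
  set.seed(seed)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sequence <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
  n_ball <- len - ARM_LEN
  # Fibonacci sphere: near-uniform points, deterministic
  k <- seq_len(n_ball)
  phi <- acos(1 - 2 * (k - 0.5) / n_ball)
  theta <- pi * (1 + sqrt(5)) * (k - 0.5)
  ca_ball <- BALL_RADIUS * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  # arm: from the ball surface out to the neighbour, with a small wobble so
  # isologous arm pairs never coincide atom-for-atom
  s <- BALL_RADIUS + 1.5 + 1.5 * (seq_len(ARM_LEN) - 1)
  wob_y <- 0.6 * sin(seq_len(ARM_LEN) + 1)
  wob_z <- 0.4 + 0.25 * seq_len(ARM_LEN)
  ca_arm <- cbind(s, wob_y, wob_z)
  ca <- rbind(ca_ball, ca_arm)
  # CB 0.8 A outward from the local origin, CG 1.6 A
  nrm <- sqrt(rowSums(ca^2)); nrm[nrm < 1e-9] <- 1
  u <- ca / nrm
  atoms <- do.call(rbind, lapply(seq_len(len), function(i) {
    data.frame(seq_pos = i,
               atom = c("CA", "CB", "CG"),
               x = ca[i, 1] + c(0, 0.8, 1.6) * u[i, 1],
               y = ca[i, 2] + c(0, 0.8, 1.6) * u[i, 2],
               z = ca[i, 3] + c(0, 0.8, 1.6) * u[i, 3],
               stringsAsFactors = FALSE)
  }))
  new_chain(chain_id, sequence, atoms, entity_key = entity_key)
}

# place the template at ring angle `deg` (degrees) on a ring of radius R at
# height z0, arm aimed at the next subunit around the ring; placements at
# successive multiples of 360/n are exact rot_z(360/n) images of each other
place_on_ring <- function(template, deg, R, z0, n_ring, chain_id) {
  alpha <- 360 / n_ring
  own <- c(R * cos(deg * pi / 180), R * sin(deg * pi / 180), z0)
  nxt <- c(R * cos((deg + alpha) * pi / 180), R * sin((deg + alpha) * pi / 180), z0)
  u <- (nxt - own); u <- u / sqrt(sum(u^2))
  ang <- atan2(u[2], u[1]) * 180 / pi   # rotation taking +x (the arm) to u
  ch <- apply_operator(template, rot_z(ang), own, id_suffix = "")
  ch$chain_id <- chain_id
  ch
}

fixture_assembly <- function(chains, assembly_id, entry_id = assembly_id,
                             space_group = NA_character_, cell = NULL,
                             method = if (is.null(cell)) "OTHER" else "XRAY") {
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  new_assembly(assembly_id, chains, entry_id = entry_id, source = "FIXTURE",
               method = method, space_group = space_group, cell = cell)
}

# assert the interface graph equals the intended edge set
assert_contact_graph <- function(assembly, edges, context) {
  got <- sort(vapply(assembly$interfaces,
                     function(f) paste(sort(f$chain_pair), collapse = "-"), ""))
  want <- sort(vapply(edges, function(e) paste(sort(e), collapse = "-"), ""))
  if (!identical(got, want))
    qc_stop("qc_fixture_error",
            "%s: interface graph {%s} != intended {%s}; adjust ring radius",
            context, paste(got, collapse = ","), paste(want, collapse = ","))
  invisible(assembly)
}

#' Ideal cyclic (Cn) assembly
#'
#' n copies of the template at exact 360/n-degree rotations about z on a ring
#' sized so adjacent chains form an interface and non-adjacent chains do not
#' (asserted at generation).
#'
#' @param template a `qc_chain` from [make_template_chain()], or a list of
#'   templates cycled around the ring (alternating entities give a
#'   hetero-oligomer with strict C(n/k) and pseudo Cn symmetry).
#' @param n ring size (>= 2).
#' @param radius ring radius in A; default sized from the neighbour distance.
#' @param z0 ring height (used by [make_dihedral()]).
#' @param assembly_id identifier.
#' @return a `qc_assembly` (FIXTURE source).
#' @export
make_cyclic <- function(template, n, radius = NULL, z0 = 0,
                        assembly_id = sprintf("C%d", n)) {
  if (n < 2) qc_stop("qc_fixture_error", "cyclic fixtures need n >= 2")
  templates <- if (inherits(template, "qc_chain")) list(template) else template
  radius <- radius %||% (NEIGHBOR_DIST / (2 * sin(pi / n)))
  chains <- lapply(seq_len(n) - 1L, function(k) {
    tpl <- templates[[(k %% length(templates)) + 1L]]
    place_on_ring(tpl, k * 360 / n, radius, z0, n, chain_id = LETTERS[k + 1L])
  })
  asm <- fixture_assembly(chains, assembly_id)
  edges <- lapply(seq_len(n), function(k)
    c(LETTERS[k], LETTERS[(k %% n) + 1L]))
  if (n == 2) edges <- edges[1]
  tryCatch(assert_contact_graph(asm, edges, assembly_id),
           qc_fixture_error = function(e)
             qc_stop("qc_fixture_error", "%s (suggested radius: %.1f A)",
                     conditionMessage(e), NEIGHBOR_DIST / (2 * sin(pi / n))))
  asm
}

#' Ideal dihedral (Dn) assembly
#'
#' Two Cn rings related by an exact 2-fold about x: the lower ring is the
#' upper ring rotated 180 degrees. Ring heights put facing subunits in
#' contact (isologous inter-ring interfaces) while cross-ring neighbours stay
#' apart.
#'
#' @param template a `qc_chain` or list of templates (one per ring gives a
#'   hetero Dn with strict Cn / pseudo Dn symmetry).
#' @param n ring size (>= 2); 2n chains total.
#' @param radius,ring_gap ring radius and half inter-ring distance (A).
#' @param assembly_id identifier.
#' @return a `qc_assembly` (FIXTURE source).
#' @export
make_dihedral <- function(template, n, radius = NULL, ring_gap = RING_HALF_GAP,
                          assembly_id = sprintf("D%d", n)) {
  if (n < 2) qc_stop("qc_fixture_error", "dihedral fixtures need n >= 2")
  templates <- if (inherits(template, "qc_chain")) list(template) else template
  tpl_top <- templates[[1]]
  tpl_bot <- templates[[min(2, length(templates))]]
  radius <- radius %||% (NEIGHBOR_DIST / (2 * sin(pi / n)))
  top <- lapply(seq_len(n) - 1L, function(k)
    place_on_ring(tpl_top, k * 360 / n, radius, ring_gap, n, LETTERS[k + 1L]))
  # bottom ring: exact 2-fold about x applied to a top-ring built from the
  # bottom template
  bot_src <- lapply(seq_len(n) - 1L, function(k)
    place_on_ring(tpl_bot, k * 360 / n, radius, ring_gap, n, "Z"))
  bot <- lapply(seq_len(n), function(k) {
    ch <- apply_operator(bot_src[[k]], rot_x(180), c(0, 0, 0), id_suffix = "")
    ch$chain_id <- letters[k]
    ch
  })
  asm <- fixture_assembly(c(top, bot), assembly_id)
  ring_edges <- function(idn) {
    e <- lapply(seq_len(n), function(k) c(idn[k], idn[(k %% n) + 1L]))
    if (n == 2) e[1] else e
  }
  # 2-fold about x maps top chain at angle a to bottom chain at angle -a:
  # top k (angle (k-1)*360/n) faces bottom chain with angle -(k-1)*360/n,
  # i.e. bottom index ((n - (k-1)) %% n) + 1
  inter <- lapply(seq_len(n), function(k)
    c(LETTERS[k], letters[((n - (k - 1L)) %% n) + 1L]))
  edges <- c(ring_edges(LETTERS[seq_len(n)]), ring_edges(letters[seq_len(n)]), inter)
  assert_contact_graph(asm, unique(lapply(edges, sort)), assembly_id)
  asm
}

mutate_sequence <- function(sequence, rate, seed) {
  set.seed(seed)
  aa <- strsplit(sequence, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) aa[i] <- sample(setdiff(alphabet, aa[i]), 1)
  paste(aa, collapse = "")
}

# replace a chain's sequence (coordinates untouched): homolog fixtures
with_sequence <- function(chain, sequence, entity_key = chain$entity_key) {
  new_chain(chain$chain_id, sequence, chain$atoms, entity_key = entity_key)
}

relabel_entity <- function(assembly, entity_key, sequence = NULL) {
  assembly$chains <- lapply(assembly$chains, function(ch)
    with_sequence(ch, sequence %||% ch$sequence, entity_key = entity_key))
  names(assembly$chains) <- vapply(assembly$chains, `[[`, "", "chain_id")
  assembly
}

#' Alpha- and beta-face D2 tetramers over one shared dimer
#'
#' Two incompatible D2 tetramers built on the same C2 dimer: the second dimer
#' copy is stacked along the dimer dyad through the subunits' -z face
#' ("alpha") or +z face ("beta"). The stacking 2-fold intersects the dimer
#' dyad perpendicular, so both tetramers are exactly D2; their inter-dimer
#' interfaces use disjoint residue caps of the ball, so the tetramers share
#' the dimer interface but never each other's inter-dimer interface.
#'
#' @param template a `qc_chain`.
#' @param face "alpha" or "beta".
#' @param assembly_id identifier.
#' @return a `qc_assembly` (FIXTURE source), D2, 4 chains.
#' @export
make_two_face_tetramer <- function(template, face = c("alpha", "beta"),
                                   assembly_id = NULL) {
  face <- match.arg(face)
  assembly_id <- assembly_id %||% sprintf("T%s", face)
  dim1 <- make_cyclic(template, 2, assembly_id = "tmp")$chains
  shift <- 2 * RING_HALF_GAP * if (face == "alpha") -1 else 1
  dim2 <- lapply(seq_along(dim1), function(k) {
    ch <- apply_operator(dim1[[k]], rot_x(180), c(0, 0, shift), id_suffix = "")
    ch$chain_id <- letters[k]
    ch
  })
  asm <- fixture_assembly(c(dim1, dim2), assembly_id)
  edges <- list(c("A", "B"), c("a", "b"), c("A", "a"), c("B", "b"))
  assert_contact_graph(asm, edges, assembly_id)
  asm
}

#' Disconnected fixture: an interacting pair plus a distant chain
#'
#' @param template a `qc_chain`.
#' @return a 3-chain `qc_assembly` that fails [is_connected()].
#' @export
make_disconnected <- function(template) {
  dim1 <- make_cyclic(template, 2, assembly_id = "tmp")$chains
  far <- apply_operator(template, diag(3), c(150, 0, 0), id_suffix = "")
  far$chain_id <- "P"
  fixture_assembly(c(dim1, list(far)), "disconnected")
}

#' Generate a toy corpus on disk
#'
#' Emits one mmCIF file per candidate assembly (file stem
#' `<entry>__<assembly>`), a domain-assignment TSV with identity HMM maps, an
#' entity TSV (entry, chain, UniProt-like key), synthetic space groups and
#' cells realizing the requested crystal-form structure, and the expected
#' cluster manifest for end-to-end tests.
#'
#' Scenarios:
#' \describe{
#'   \item{shared_dimer}{`n_entries` homolog entries, each one C2 dimer,
#'     spread over `n_cfs` crystal forms. Manifest: one A2 cluster.}
#'   \item{two_dimer_faces}{six homolog entries, each holding the common C2
#'     dimer plus one of two incompatible D2 tetramers (three alpha, three
#'     beta), one crystal form each. Manifest: one A2 cluster spanning all
#'     entries and two disjoint A4 clusters.}
#'   \item{disconnected}{one extra entry whose only candidate assembly has a
#'     chain out of contact; the pipeline must exclude and log it.}
#' }
#'
#' @param dir output directory (created).
#' @param scenario one of the above.
#' @param n_entries,n_cfs scenario size (shared_dimer only).
#' @param template_len residues per chain.
#' @param seed RNG seed for sequences.
#' @return list(dir, files, assignments, entities, manifest, corpus_cfs).
#' @export
make_toy_corpus <- function(dir, scenario = c("two_dimer_faces", "shared_dimer",
                                              "disconnected"),
                            n_entries = 6, n_cfs = 3, template_len = 30, seed = 1) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- make_template_chain(template_len, seed = seed)
  if (scenario == "shared_dimer") {
    specs <- lapply(seq_len(n_entries), function(k)
      list(entry = sprintf("E%02d", k), kinds = "dimer",
           cf = ((k - 1) %% n_cfs) + 1L))
  } else if (scenario == "two_dimer_faces") {
    n_entries <- 6
    specs <- lapply(seq_len(n_entries), function(k)
      list(entry = sprintf("E%02d", k),
           kinds = c("dimer", if (k <= 3) "alpha" else "beta"),
           cf = k))
  } else {
    specs <- list(list(entry = "E99", kinds = "disconnected", cf = 1L))
  }
  files <- character(0)
  entities <- NULL; assignments <- NULL
  cells <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    unp <- sprintf("UNP%02d", k)
    seqk <- if (k == 1) base$sequence else
      mutate_sequence(base$sequence, rate = 0.4, seed = seed + 100 + k)
    tpl <- with_sequence(base, seqk, entity_key = unp)
    # one synthetic cell per CF; same cell (within 1%) inside a CF
    cell <- c(60, 70, 80, 90, 90, 90) * (1 + 0.1 * (sp$cf - 1)) *
      (1 + 0.002 * (k %% 2))
    sg <- "P 21 21 21"
    for (kind in sp$kinds) {
      asm <- switch(kind,
        dimer = make_cyclic(tpl, 2, assembly_id = paste0(sp$entry, "-dim")),
        alpha = make_two_face_tetramer(tpl, "alpha",
                                       assembly_id = paste0(sp$entry, "-ta")),
        beta = make_two_face_tetramer(tpl, "beta",
                                      assembly_id = paste0(sp$entry, "-tb")),
        disconnected = make_disconnected(tpl))
      asm$entry_id <- sp$entry
      f <- file.path(dir, sprintf("%s__%s.cif", sp$entry,
                                  sub("^.*-", "", asm$assembly_id)))
      write_assembly(asm, f, format = "mmCIF", method = "XRAY",
                     space_group = sg, cell = cell)
      files <- c(files, f)
      entities <- rbind(entities, data.frame(
        entry_id = sp$entry, chain_id = names(asm$chains), unp = unp,
        stringsAsFactors = FALSE))
      assignments <- rbind(assignments, data.frame(
        entry_id = sp$entry, chain_id = names(asm$chains), pfam_id = "TOY",
        seq_start = 1L, seq_end = template_len, hmm_map = "",
        stringsAsFactors = FALSE))
    }
    cells[[sp$entry]] <- list(cell = cell, sg = sg, cf = sp$cf)
  }
  entities <- unique(entities)
  assignments <- unique(assignments)
  asg_path <- file.path(dir, "assignments.tsv")
  utils::write.table(assignments, asg_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ent_path <- file.path(dir, "entities.tsv")
  utils::write.table(entities, ent_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest <- switch(scenario,
    shared_dimer = data.frame(stoichiometry = "A2", symmetry = "C2",
                              n_members = as.integer(n_entries),
                              n_cfs = length(unique(vapply(specs, function(sp) as.integer(sp$cf), integer(1))))),
    two_dimer_faces = data.frame(
      stoichiometry = c("A2", "A4", "A4"), symmetry = c("C2", "D2", "D2"),
      n_members = c(6L, 3L, 3L), n_cfs = c(6L, 3L, 3L)),
    disconnected = data.frame(stoichiometry = character(0),
                              symmetry = character(0),
                              n_members = integer(0), n_cfs = integer(0)))
  n_cf_total <- length(unique(vapply(specs, function(sp) as.integer(sp$cf), integer(1))))
  corpus_cfs <- stats::setNames(
    vapply(seq_along(specs), function(k) 1L, integer(1)),
    sprintf("UNP%02d", seq_along(specs)))
  if (scenario == "shared_dimer") {
    # entities sharing a CF still count that CF once each
    for (k in seq_along(specs)) corpus_cfs[k] <- 1L
  }
  list(dir = dir, files = files, assignments = asg_path, entities = ent_path,
       manifest = manifest, corpus_cfs = corpus_cfs, n_cfs = n_cf_total)
}
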