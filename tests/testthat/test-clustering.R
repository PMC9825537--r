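# Binary assembly similarity, clustering, and cluster statistics.

test_that("binary similarity is reflexive, symmetric, and rigid-body invariant", {
  tpl <- tpl30()
  a <- annotate_assembly(make_cyclic(tpl, 3, assembly_id = "a1"))
  expect_equal(assembly_similarity(a, a)$s, 1L)

  b <- annotate_assembly(rigid_move(make_cyclic(tpl, 3, assembly_id = "a2"), seed = 8))
  sab <- assembly_similarity(a, b); sba <- assembly_similarity(b, a)
  expect_equal(sab$s, 1L)
  expect_identical(sab$s, sba$s)
  expect_identical(c(sab$s12, sab$s21), c(sba$s21, sba$s12))
  expect_equal(sab$s, sab$s12 * sab$s21)
})

test_that("incompatible D2 tetramers over one dimer: s = 0, verified per interface", {
  tpl <- tpl30()
  ta <- annotate_assembly(make_two_face_tetramer(tpl, "alpha"))
  tb <- annotate_assembly(make_two_face_tetramer(tpl, "beta"))
  expect_equal(assembly_similarity(ta, tb)$s, 0L)
  # oracle: explicit Q between the interface representatives; the shared
  # dimer interface matches, the inter-dimer ones do not reach q_match
  ica <- connecting_interfaces(ta); icb <- connecting_interfaces(tb)
  qmat <- outer(ica$connecting, icb$representatives, Vectorize(function(i, j)
    qscore(ta$interfaces[[i]], tb$interfaces[[j]])$value))
  expect_true(any(qmat >= 0.5))             # the dimer interface
  expect_true(any(apply(qmat, 1, max) < 0.5))  # the incompatible one
  # the comparison gate refuses cross-cell calls
  dimer <- annotate_assembly(make_cyclic(tpl, 2, assembly_id = "d"))
  expect_error(assembly_similarity(ta, dimer), class = "qc_incomparable")
})

test_that("clustering partitions cells, never mixes them, and ignores input order", {
  tpl <- tpl30()
  mk <- function(ctor, id, seed) {
    a <- ctor(id)
    if (!is.null(seed)) a <- rigid_move(a, seed)
    annotate_assembly(a)
  }
  asms <- list(
    mk(function(id) make_cyclic(tpl, 3, assembly_id = id), "t1", NULL),
    mk(function(id) make_cyclic(tpl, 3, assembly_id = id), "t2", 31),
    mk(function(id) make_cyclic(tpl, 3, assembly_id = id), "t3", 32),
    mk(function(id) make_cyclic(tpl, 2, assembly_id = id), "d1", NULL),
    mk(function(id) make_cyclic(tpl, 2, assembly_id = id), "d2", 33),
    mk(function(id) make_two_face_tetramer(tpl, "alpha", assembly_id = id), "x1", NULL),
    mk(function(id) make_two_face_tetramer(tpl, "beta", assembly_id = id), "x2", 34))
  cf <- stats::setNames(1:7, c("t1", "t2", "t3", "d1", "d2", "x1", "x2"))
  for (k in seq_along(asms)) asms[[k]]$entry_id <- asms[[k]]$assembly_id
  cl <- cluster_assemblies(asms, cf_ids = cf)
  key <- function(cl) vapply(cl, function(x)
    paste(x$stoichiometry, x$symmetry, x$n_entries, x$n_cfs), "")
  expect_setequal(key(cl), c("A3 C3 3 3", "A2 C2 2 2", "A4 D2 1 1", "A4 D2 1 1"))
  # trimers never co-cluster with dimers; each assembly in exactly one cluster
  members <- unlist(lapply(cl, function(x)
    vapply(x$members, function(m) m$assembly$assembly_id, "")))
  expect_setequal(members, names(cf))
  expect_equal(anyDuplicated(members), 0L)
  # input order invariance
  set.seed(1); cl2 <- cluster_assemblies(asms[sample(7)], cf_ids = cf)
  expect_identical(key(cl), key(cl2))
  expect_identical(lapply(cl, `[[`, "members"), lapply(cl2, `[[`, "members"))
  # three copies of one assembly from three CFs: one cluster with n_cfs = 3
  expect_equal(cl[[1]]$n_cfs, 3)
})

test_that("R_CF_UNPclus reproduces the worked ratios 5/7 = 0.71 and 21/21 = 1.0", {
  cl_members <- function(assign) {
    # assign: list of (unp, cf_id)
    structure(list(members = lapply(assign, function(x)
      list(assembly = NULL, entry_id = x[[1]], cf_id = x[[2]],
           entity_keys = x[[1]]))), class = "qc_assembly_cluster")
  }
  # one protein: 5 cluster CFs of 7 corpus CFs
  tthy <- cl_members(lapply(1:5, function(k) list("TTHY_HUMAN", k)))
  st <- r_cf_unpclus(tthy, c(TTHY_HUMAN = 7L))
  expect_equal(st$per_unp$r_cf_unpclus, 5 / 7)
  expect_identical(st$text, "0.71")
  # 12 proteins over 21 CFs, corpus CFs identical: cluster ratio 1.0
  counts <- c(rep(2L, 9), 1L, 1L, 1L)  # 9*2 + 3 = 21
  assign <- list(); cf <- 0L
  for (u in seq_along(counts)) for (k in seq_len(counts[u])) {
    cf <- cf + 1L
    assign[[length(assign) + 1L]] <- list(sprintf("UNP%02d", u), cf)
  }
  big <- cl_members(assign)
  corpus <- stats::setNames(counts, sprintf("UNP%02d", seq_along(counts)))
  stb <- r_cf_unpclus(big, corpus)
  expect_equal(sum(stb$per_unp$cf_unpclus), 21)
  expect_equal(stb$r_cf_unpclus, 1.0)
  # single-CF protein
  one <- cl_members(list(list("U1", 1L)))
  expect_equal(r_cf_unpclus(one, c(U1 = 1L))$r_cf_unpclus, 1.0)
  # corpus inconsistencies are errors, not silent clamps
  expect_error(r_cf_unpclus(one, c(U1 = 0L)), class = "qc_data_inconsistency")
  expect_error(r_cf_unpclus(tthy, c(TTHY_HUMAN = 3L)),
               class = "qc_data_inconsistency")
})

test_that("annotation agreement counts matching labels; absent table means absent counts", {
  tpl <- tpl30()
  ta <- annotate_assembly(make_two_face_tetramer(tpl, "alpha", assembly_id = "e1"))
  ta$entry_id <- "e1"
  cl <- structure(list(cluster_id = "c1",
                       members = list(list(assembly = ta, entry_id = "e1",
                                           cf_id = 1L, entity_keys = "U1"))),
                  class = "qc_assembly_cluster")
  same <- annotate_assembly(make_two_face_tetramer(tpl, "alpha", assembly_id = "e1x"))
  half <- annotate_assembly(make_cyclic(tpl, 2, assembly_id = "e1h"))
  other <- annotate_assembly(make_two_face_tetramer(tpl, "beta", assembly_id = "e1b"))
  ann <- list(list(entry_id = "e1", source = "PDB", assembly = same),
              list(entry_id = "e1", source = "PISA", assembly = half),
              list(entry_id = "e1", source = "EPPIC", assembly = other))
  counts <- annotation_agreement(cl, ann)
  expect_identical(counts[["PDB"]], 1L)
  expect_identical(counts[["PISA"]], 0L)   # stoichiometry gate: half a tetramer
  expect_identical(counts[["EPPIC"]], 0L)  # different tetramer face
  expect_null(annotation_agreement(cl, NULL))
})

test_that("identity statistics separate intra- from inter-cluster sequence pairs", {
  tpl <- tpl30()
  mk_cluster <- function(id, seqs, cf_ids) {
    members <- lapply(seq_along(seqs), function(k) {
      ch <- quatclust:::with_sequence(tpl, seqs[k], entity_key = paste0(id, "u", k))
      asm <- annotate_assembly(make_cyclic(ch, 2, assembly_id = paste0(id, k)))
      list(assembly = asm, entry_id = paste0(id, k), cf_id = cf_ids[k],
           entity_keys = paste0(id, "u", k))
    })
    structure(list(cluster_id = id, members = members, n_cfs = length(unique(cf_ids))),
              class = "qc_assembly_cluster")
  }
  s <- tpl$sequence
  near <- quatclust:::mutate_sequence(s, 0.2, 41)
  far1 <- quatclust:::mutate_sequence(s, 0.9, 42)
  far2 <- quatclust:::mutate_sequence(far1, 0.2, 43)
  c1 <- mk_cluster("a", c(s, near), 1:2)
  c2 <- mk_cluster("b", c(far1, far2), 3:4)
  st <- identity_stats(list(c1, c2), min_cfs = 2)
  expect_length(st$intra, 2)
  expect_length(st$inter, 1)
  expect_gt(min(st$intra), st$inter)
  # identical sequences: intra exactly 100; single cluster: inter empty
  cid <- mk_cluster("c", c(s, s), 1:2)
  cid$members[[2]]$entity_keys <- "cu2"
  st2 <- identity_stats(list(cid), min_cfs = 2)
  expect_equal(st2$intra, 100)
  expect_length(st2$inter, 0)
})
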