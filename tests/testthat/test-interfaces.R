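# Interface detection criteria and the interface Q score.

test_that("contact_pairs equals the brute-force double-loop scan", {
  tpl <- tpl30()
  c3 <- make_cyclic(tpl, 3)
  a <- c3$chains[["A"]]; b <- c3$chains[["B"]]; c <- c3$chains[["C"]]
  for (pair in list(list(a, b), list(b, c), list(a, c))) {
    got <- contact_pairs(pair[[1]], pair[[2]])
    want <- brute_contacts(pair[[1]], pair[[2]])
    key <- function(df) if (is.null(df) || nrow(df) == 0) character(0) else
      sort(paste(df$pos_i, df$pos_j))
    expect_identical(key(got$cb_pairs), key(want$cb))
    expect_identical(key(got$atomic5_pairs), key(want$at))
    if (nrow(got$cb_pairs) > 0) {
      want_d <- want$cb$d[order(paste(want$cb$pos_i, want$cb$pos_j))]
      got_d <- got$cb_pairs$d[order(paste(got$cb_pairs$pos_i, got$cb_pairs$pos_j))]
      expect_equal(got_d, want_d, tolerance = 1e-9)
    }
  }
  far <- apply_operator(a, diag(3), c(100, 0, 0))
  cp <- contact_pairs(a, far)
  expect_equal(nrow(cp$cb_pairs), 0)
  expect_equal(nrow(cp$atomic5_pairs), 0)
})

test_that("interface criterion enforces both disjuncts at their boundaries", {
  # exactly 10 representative pairs within 12 A and exactly 1 atomic contact
  ca_a <- cbind(0, 30 * (0:9), 0)
  ca_b <- cbind(10, 30 * (0:9), 0)
  a <- point_chain("A", ca_a)
  b10 <- point_chain("B", ca_b,
                     extra_atoms = data.frame(seq_pos = 1L, atom = "CG",
                                              x = 4.5, y = 0, z = 0))
  cp <- contact_pairs(a, b10)
  expect_equal(nrow(cp$cb_pairs), 10)
  expect_equal(nrow(cp$atomic5_pairs), 1)
  expect_true(is_interface(a, b10))

  # 9 representative pairs, 4 atomic contacts: neither disjunct holds
  a9 <- point_chain("A", ca_a[1:9, , drop = FALSE])
  b9 <- point_chain("B", ca_b[1:9, , drop = FALSE],
                    extra_atoms = data.frame(seq_pos = 1:4, atom = "CG",
                                             x = 4.5, y = 30 * (0:3), z = 0))
  cp9 <- contact_pairs(a9, b9)
  expect_equal(nrow(cp9$cb_pairs), 9)
  expect_equal(nrow(cp9$atomic5_pairs), 4)
  expect_false(is_interface(a9, b9))

  # 0 representative pairs but 5 atomic contacts (long side-chain contacts)
  aL <- point_chain("A", cbind(0, 40 * (0:4), 0),
                    extra_atoms = data.frame(seq_pos = 1:5, atom = "CG",
                                             x = 1000 + 30 * (0:4), y = 0, z = 0))
  bL <- point_chain("B", cbind(500, 40 * (0:4), 0),
                    extra_atoms = data.frame(seq_pos = 1:5, atom = "CG",
                                             x = 1002 + 30 * (0:4), y = 0, z = 0))
  cpL <- contact_pairs(aL, bL)
  expect_equal(nrow(cpL$cb_pairs), 0)
  expect_equal(nrow(cpL$atomic5_pairs), 5)
  expect_true(is_interface(aL, bL))
})

test_that("find_interfaces matches the all-pairs oracle on small assemblies", {
  tpl <- tpl30()
  for (asm in list(make_cyclic(tpl, 3), make_cyclic(tpl, 4),
                   make_dihedral(tpl, 2), make_dihedral(tpl, 4))) {
    ids <- names(asm$chains)
    want <- character(0)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      bc <- brute_contacts(asm$chains[[ids[i]]], asm$chains[[ids[j]]])
      n_cb <- if (is.null(bc$cb)) 0 else nrow(bc$cb)
      n_at <- if (is.null(bc$at)) 0 else nrow(bc$at)
      if ((n_cb >= 10 && n_at >= 1) || n_at >= 5)
        want <- c(want, paste(sort(c(ids[i], ids[j])), collapse = "-"))
    }
    got <- vapply(asm$interfaces,
                  function(f) paste(sort(f$chain_pair), collapse = "-"), "")
    expect_setequal(got, want)
  }
  mono <- new_assembly("m", list(A = tpl))
  expect_length(mono$interfaces, 0)
})

test_that("Q score: identity is 1, hand-worked sets score as set arithmetic says", {
  tpl <- tpl30()
  f <- make_cyclic(tpl, 3)$interfaces
  expect_equal(qscore(f[[1]], f[[1]])$value, 1)
  expect_equal(qscore(f[[1]], f[[1]], weight_mode = "distance")$value, 1)

  # P1 = {(1,1),(1,2),(2,2)}, P2 = {(1,1),(2,2),(3,3)} -> 2 common, 4 union
  mk_iface <- function(pairs) {
    structure(list(interface_id = 1L, chain_pair = c("A", "B"),
                   contact_pairs = data.frame(pos_i = pairs[, 1],
                                              pos_j = pairs[, 2], d = 5),
                   n_cb_12A = nrow(pairs), n_atomic_5A = 1L,
                   area_proxy = nrow(pairs)), class = "qc_interface")
  }
  i1 <- mk_iface(rbind(c(1, 1), c(1, 2), c(2, 2)))
  i2 <- mk_iface(rbind(c(1, 1), c(2, 2), c(3, 3)))
  q <- qscore(i1, i2, try_swap = FALSE)
  expect_equal(q$value, 0.5)
  expect_equal(q$n_common, 2L)
  expect_equal(q$n_union, 4L)

  i3 <- mk_iface(rbind(c(7, 8), c(8, 9)))
  expect_equal(qscore(i1, i3)$value, 0)
})

test_that("Q score is symmetric, bounded, and distance mode never exceeds jaccard", {
  tpl <- tpl30()
  asm <- make_dihedral(tpl, 3)
  fs <- asm$interfaces
  set.seed(3)
  picks <- t(replicate(12, sample(length(fs), 2)))
  for (k in seq_len(nrow(picks))) {
    f1 <- fs[[picks[k, 1]]]; f2 <- fs[[picks[k, 2]]]
    qj <- qscore(f1, f2)$value
    qd <- qscore(f1, f2, weight_mode = "distance")$value
    expect_equal(qj, qscore(f2, f1)$value)
    expect_equal(qd, qscore(f2, f1, weight_mode = "distance")$value)
    expect_gte(qj, 0); expect_lte(qj, 1)
    expect_lte(qd, qj + 1e-12)
  }
  # position maps: dropping unmapped positions and erroring on empty maps
  f1 <- fs[[1]]
  empty_map <- list(a = stats::setNames(integer(0), character(0)),
                    b = stats::setNames(integer(0), character(0)))
  expect_error(qscore(f1, f1, map1 = empty_map, map2 = empty_map),
               class = "qc_qscore_undefined")
})
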