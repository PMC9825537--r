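# Assembly construction, connectivity, and the unique-connecting-interface
# reduction.

test_that("build_assembly instantiates operator specs and validates chain ids", {
  tpl <- tpl30()
  chB <- apply_operator(tpl, diag(3), c(0, 25, 0), id_suffix = "")
  chB$chain_id <- "B"
  st <- new_structure_model("ENT1", list(A = tpl, B = chB), method = "OTHER")
  asm <- build_assembly(st)
  expect_length(asm$chains, 2)

  # one chain replicated under three 120-degree rotations closes a C3 ring
  r120 <- quatclust:::rot_z(120)
  c3ring <- make_cyclic(tpl, 3)
  stA <- new_structure_model("ENT2", list(A = c3ring$chains[["A"]]), method = "OTHER")
  spec <- operator_spec(c("A", "A", "A"),
                        rots = list(diag(3), r120, r120 %*% r120))
  asm3 <- build_assembly(stA, spec)
  expect_length(asm3$chains, 3)
  # rotation closure: the instantiated chains reproduce the ring coordinates
  got <- chain_xyz_(asm3$chains[[2]])
  want <- chain_xyz_(c3ring$chains[["B"]])
  expect_lt(max(abs(got - want)), 1e-9)
  expect_length(asm3$interfaces, 3)

  expect_error(build_assembly(st, operator_spec(c("A", "Q"))),
               class = "qc_spec_error")
})

test_that("connectivity: monomer and rings are connected, stray chains are not", {
  tpl <- tpl30()
  expect_true(is_connected(new_assembly("m", list(A = tpl))))
  expect_true(is_connected(make_cyclic(tpl, 3)))
  expect_false(is_connected(make_disconnected(tpl)))
  # an assembly built from a spec that throws one chain 100 A away
  st <- new_structure_model("E", list(A = tpl), method = "OTHER")
  spec <- operator_spec(c("A", "A"), transs = list(c(0, 0, 0), c(100, 0, 0)))
  expect_false(is_connected(build_assembly(st, spec)))
})

test_that("unique_interfaces equals exhaustive pairwise-Q transitive closure", {
  tpl <- tpl30()
  for (asm in list(make_cyclic(tpl, 4), make_dihedral(tpl, 2),
                   make_dihedral(tpl, 3))) {
    ucs <- unique_interfaces(asm)
    fs <- asm$interfaces
    n <- length(fs)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- qscore(fs[[i]], fs[[j]])$value >= 0.75
    want <- closure_membership(adj)
    got <- integer(n)
    for (k in seq_along(ucs$clusters)) got[ucs$clusters[[k]]] <- k
    # same partition (labels may differ)
    expect_equal(length(unique(want)), length(unique(got)))
    for (i in seq_len(n)) for (j in seq_len(n))
      expect_equal(want[i] == want[j], got[i] == got[j])
    # representative is the smallest member id; order is by descending area
    for (k in seq_along(ucs$clusters))
      expect_equal(ucs$representatives[k], min(ucs$clusters[[k]]))
    areas <- vapply(ucs$representatives, function(id)
      fs[[id]]$area_proxy, numeric(1))
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("a C4 ring has one interface cluster; D2 has at least two", {
  tpl <- tpl30()
  expect_length(unique_interfaces(make_cyclic(tpl, 4))$clusters, 1)
  expect_gte(length(unique_interfaces(make_dihedral(tpl, 2))$clusters), 2)
  one <- make_cyclic(tpl, 2)
  expect_length(unique_interfaces(one)$clusters, 1)
})

test_that("connecting interfaces: one per Cn ring, two for D2, >=2 for D3", {
  tpl <- tpl30()
  for (n in 3:8)
    expect_length(connecting_interfaces(make_cyclic(tpl, n))$connecting, 1)
  expect_length(connecting_interfaces(make_dihedral(tpl, 2))$connecting, 2)
  expect_gte(length(connecting_interfaces(make_dihedral(tpl, 3))$connecting), 2)
  # connecting is a subset of representatives; identical input, identical output
  d3 <- make_dihedral(tpl, 3)
  ic1 <- connecting_interfaces(d3); ic2 <- connecting_interfaces(d3)
  expect_true(all(ic1$connecting %in% ic1$representatives))
  expect_identical(ic1, ic2)
  expect_error(connecting_interfaces(make_disconnected(tpl)),
               class = "qc_assembly_error")
})

test_that("merge_candidates deduplicates by similarity but never across stoichiometries", {
  tpl <- tpl30()
  dim1 <- annotate_assembly(make_cyclic(tpl, 2, assembly_id = "d1"))
  dim2 <- annotate_assembly(make_cyclic(tpl, 2, assembly_id = "d2"))
  expect_length(merge_candidates(list(dim1, dim2)), 1)

  tet <- annotate_assembly(make_dihedral(tpl, 2, assembly_id = "t1"))
  expect_length(merge_candidates(list(dim1, tet)), 2)

  # two distinct dimers of the same chains: the shared-arm dimer versus a
  # ball-face dimer extracted from a tetramer
  alt <- annotate_assembly(make_two_face_tetramer(tpl, "alpha"))
  face_dimer <- new_assembly("fd", alt$chains[c("A", "a")], source = "GENERATED")
  face_dimer <- annotate_assembly(face_dimer)
  expect_length(merge_candidates(list(dim1, face_dimer)), 2)
  # and their interfaces really differ under Q
  q <- qscore(dim1$interfaces[[1]], face_dimer$interfaces[[1]])$value
  expect_lt(q, 0.5)

  # GENERATED preferred over DEPOSITED on duplicates
  dep <- dim2; dep$source <- "DEPOSITED"
  gen <- dim1; gen$source <- "GENERATED"
  kept <- merge_candidates(list(dep, gen))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$source, "GENERATED")
})
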