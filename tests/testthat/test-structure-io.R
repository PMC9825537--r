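# Structure model, rigid operators, and file round-trips.

test_that("apply_operator is exact for identity, involutive for 2-folds, and rigid", {
  tpl <- tpl30()
  id <- apply_operator(tpl, diag(3), c(0, 0, 0))
  expect_identical(chain_xyz_(id), chain_xyz_(tpl))
  expect_identical(id$sequence, tpl$sequence)

  rz <- quatclust:::rot_z(180)
  twice <- apply_operator(apply_operator(tpl, rz, c(1, 2, 3)), rz, -c(1, 2, 3) %*% t(rz))
  # R(Rx + t) + t2 with t2 = -R t returns the original coordinates
  expect_lt(max(abs(chain_xyz_(twice) - chain_xyz_(tpl))), 1e-9)

  set.seed(11)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- apply_operator(tpl, q, rnorm(3, sd = 30))
  d0 <- dist(chain_xyz_(tpl)); d1 <- dist(chain_xyz_(moved))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  bad <- diag(3); bad[1, 1] <- 1.01
  expect_error(apply_operator(tpl, bad), class = "qc_operator_error")
})

test_that("mmCIF and PDB round-trips preserve chains, sequences and coordinates", {
  tpl <- tpl30()
  c3 <- make_cyclic(tpl, 3)
  td <- withr::local_tempdir()
  for (fmt in c("mmCIF", "PDB")) {
    f <- file.path(td, paste0("c3.", if (fmt == "mmCIF") "cif" else "pdb"))
    write_assembly(c3, f, format = fmt, method = "XRAY",
                   space_group = "P 21 21 21", cell = c(60, 70, 80, 90, 90, 90))
    st <- read_structure(f)
    expect_length(st$chains, 3)
    expect_identical(st$method, "XRAY")
    expect_identical(st$space_group, "P 21 21 21")
    expect_equal(st$cell, c(60, 70, 80, 90, 90, 90), tolerance = 1e-6)
    for (cid in names(c3$chains)) {
      expect_identical(st$chains[[cid]]$sequence, c3$chains[[cid]]$sequence)
      expect_lt(max(abs(chain_xyz_(st$chains[[cid]]) - chain_xyz_(c3$chains[[cid]]))),
                0.001)
    }
  }
  # the two format routes (own mmCIF reader vs bio3d PDB reader) agree
  a <- read_structure(file.path(td, "c3.cif"))
  b <- read_structure(file.path(td, "c3.pdb"))
  expect_lt(max(abs(chain_xyz_(a$chains[["A"]]) - chain_xyz_(b$chains[["A"]]))), 0.002)
})

test_that("D2 tetramer round-trips with 4 chains; >62 chains refused in PDB", {
  tpl <- tpl30()
  d2 <- make_dihedral(tpl, 2)
  td <- withr::local_tempdir()
  f <- file.path(td, "d2.cif")
  write_assembly(d2, f)
  expect_length(read_structure(f)$chains, 4)

  big <- d2
  big$chains <- stats::setNames(rep(d2$chains, 16), sprintf("X%02d", 1:64))
  expect_error(write_assembly(big, file.path(td, "big.pdb"), format = "PDB"),
               class = "qc_io_error")
})

test_that("reader maps methods, skips unresolved chains, waters and altlocs", {
  td <- withr::local_tempdir()
  f <- file.path(td, "em.cif")
  # hand-built file: chain A with 3 residues (one with an altloc pair), a
  # water, and chain B present only in the entity list (zero atoms)
  writeLines(c(
    "data_TEST",
    "_entry.id TEST",
    "_exptl.method 'ELECTRON MICROSCOPY'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 A 1 0.0 0.0 0.0 1.00 0.00 1",
    "ATOM 2 C CB A ALA A 1 A 1 1.0 0.0 0.0 0.40 0.00 1",
    "ATOM 3 C CB B ALA A 1 A 1 2.0 0.0 0.0 0.60 0.00 1",
    "ATOM 4 C CA . GLY A 2 A 2 3.8 0.0 0.0 1.00 0.00 1",
    "ATOM 5 C CA . SER A 3 A 3 7.6 0.0 0.0 1.00 0.00 1",
    "HETATM 6 O O . HOH W 1 W 1 9.0 9.0 9.0 1.00 0.00 1",
    "#"), f)
  st <- read_structure(f)
  expect_identical(st$method, "EM")
  expect_length(st$chains, 1)            # only chain A carries atoms
  ch <- st$chains[["A"]]
  expect_identical(ch$sequence, "AGS")
  # highest-occupancy altloc kept: CB at x = 2.0
  cb <- ch$atoms[ch$atoms$atom == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2.0)
  # representative point: CB for ALA, CA for GLY
  expect_equal(unname(ch$rep$xyz[1, 1]), 2.0)
  expect_equal(unname(ch$rep$xyz[2, 1]), 3.8)
})

test_that("read_structure errors are classed and informative", {
  td <- withr::local_tempdir()
  expect_error(read_structure(file.path(td, "nope.cif")), class = "qc_io_error")
  f <- file.path(td, "empty.cif")
  writeLines(c("data_X", "_entry.id X"), f)
  expect_error(read_structure(f), class = "qc_empty_structure")
})

test_that("alignment scripts load every member and superpose all but the representative", {
  tpl <- tpl30()
  mk <- function(id) {
    a <- annotate_assembly(make_cyclic(tpl, 3, assembly_id = id))
    list(assembly = a, entry_id = id, cf_id = 1L, entity_keys = "U1")
  }
  cl1 <- structure(list(cluster_id = "clus001", members = list(mk("m1")),
                        representative = "m1"), class = "qc_assembly_cluster")
  cl3 <- structure(list(cluster_id = "clus002",
                        members = list(mk("m1"), mk("m2"), mk("m3")),
                        representative = "m1"), class = "qc_assembly_cluster")
  td <- withr::local_tempdir()
  p1 <- file.path(td, "one.pml")
  write_alignment_script(cl1, p1)
  lines1 <- readLines(p1)
  expect_length(grep("^load ", lines1), 1)
  expect_length(grep("^align ", lines1), 0)

  manifest <- write_cluster_bundle(cl3, file.path(td, "bundle"))
  p3 <- file.path(td, "bundle", "align.pml")
  write_alignment_script(cl3, p3, files = basename(manifest))
  lines3 <- readLines(p3)
  expect_length(grep("^load ", lines3), 3)
  expect_length(grep("^align ", lines3), 2)
  # script references exactly the bundle manifest files
  loaded <- sub("^load ([^,]+),.*$", "\\1", grep("^load ", lines3, value = TRUE))
  expect_setequal(loaded, basename(manifest))
  expect_true(all(file.exists(manifest)))
})
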