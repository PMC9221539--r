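test_that("a minimal PDB file parses with coordinates, metadata and B-factors intact", {
  path <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(path)
  expect_s3_class(s, "structure_model")
  expect_equal(nrow(residues(s)), 3)
  expect_equal(coords_of(s)[, 1], c(0, 3.8, 7.6))
  expect_equal(s$b, rep(20, 3))
  expect_equal(attr(s, "resolution"), 1.5)
  expect_equal(attr(s, "space_group"), "P 21 21 21")
  expect_equal(attr(s, "source"), "crystal")
})

test_that("the same content read from mmCIF gives an identical structure", {
  pdb <- read_structure(write_mini_pdb(withr::local_tempfile(fileext = ".pdb")))
  cif <- read_structure(write_mini_cif(withr::local_tempfile(fileext = ".cif")))
  expect_equal(coords_of(cif), coords_of(pdb))
  expect_equal(cif$resno, pdb$resno)
  expect_equal(cif$resid, pdb$resid)
  expect_equal(cif$b, pdb$b)
  expect_equal(attr(cif, "resolution"), attr(pdb, "resolution"))
  expect_equal(attr(cif, "space_group"), attr(pdb, "space_group"))
})

test_that("the highest-occupancy altloc conformer is kept", {
  path <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"), altloc_block = TRUE)
  s <- read_structure(path)
  expect_equal(nrow(s), 3)                       # one CA per residue
  expect_equal(unname(coords_of(s)[1, 1]), 0)    # altloc A (occ 0.6), not B at x=5
  # when B carries the higher occupancy it must win over file order
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 20.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 20.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00 20.00           C",
    "END"), path2)
  s2 <- read_structure(path2)
  expect_equal(unname(coords_of(s2)[1, 1]), 5)
  # ties break to the first conformer encountered
  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50 20.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.50 20.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00 20.00           C",
    "END"), path3)
  expect_equal(unname(coords_of(read_structure(path3))[1, 1]), 1)
})

test_that("write/read round trip preserves the structure to PDB precision", {
  ens <- make_ensemble(n_residues = 40, n_members = 1, sigma = 0.3, seed = 3)
  s <- ens$structures$m1
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path, source = "crystal")
  expect_equal(coords_of(s2), coords_of(s), tolerance = 1e-3)
  expect_equal(s2$resno, s$resno)
  expect_equal(s2$elety, s$elety)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, path2)
  s3 <- read_structure(path2, source = "crystal")
  expect_identical(coords_of(s3), coords_of(s2))  # fixed point after one pass
})

test_that("unreadable and empty files raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a pdb file at all", bad)
  expect_error(read_structure(bad))
  expect_error(read_structure(file.path(tempdir(), "absent.pdb")), "not found")
})

test_that("correspondence pairs residues by author numbering and respects gaps", {
  a <- build_helix(12)
  b_atoms <- tibble::as_tibble(build_helix(12))
  b <- structure_model(b_atoms[!b_atoms$resno %in% 5:7, ], id = "gapped")
  map <- build_correspondence(a, b, "calpha")
  expect_equal(nrow(map), 9)
  expect_false(any(grepl(":5:|:6:|:7:", map$id_a)))
  # identical structures pair everything
  full <- build_correspondence(a, a, "calpha")
  expect_equal(nrow(full), 12)
  # symmetry: swapping arguments swaps the tuple order
  map_ba <- build_correspondence(b, a, "calpha")
  expect_equal(map$id_a, map_ba$id_b)
  expect_equal(map$id_b, map_ba$id_a)
})

test_that("residues lacking the atoms demanded by the level are excluded", {
  a <- build_helix(10)
  b_atoms <- tibble::as_tibble(build_helix(10))
  b_atoms$elety[b_atoms$resno == 4] <- "CB"     # residue 4 has no CA
  b <- structure_model(b_atoms, id = "noca")
  map <- build_correspondence(a, b, "calpha")
  expect_equal(nrow(map), 9)
  # disjoint residue sets error
  c_atoms <- tibble::as_tibble(build_helix(5))
  c_atoms$resno <- c_atoms$resno + 100
  expect_error(build_correspondence(a, structure_model(c_atoms), "calpha"),
               "no common residues")
})

test_that("chain mapping and name mismatches are handled", {
  a <- build_helix(6)
  b_atoms <- tibble::as_tibble(build_helix(6))
  b_atoms$chain <- "B"
  b_atoms$resid[2] <- "GLY"
  b <- structure_model(b_atoms, id = "chB")
  expect_error(build_correspondence(a, b, "calpha"), "no common residues")
  expect_warning(map <- build_correspondence(a, b, "calpha", chain_map = c(A = "B")),
                 "mismatch")
  expect_equal(nrow(map), 6)
  expect_equal(sum(map$name_mismatch), 1)
})

test_that("profiles carry the C-alpha temperature factor per residue", {
  path <- write_mini_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(path)
  prof <- extract_profile(s, "bfactor")
  expect_equal(prof$value, rep(20, 3))
  expect_equal(nrow(prof), nrow(residues(s)))
  # pLDDT path validates the 0-100 range
  ens <- make_ensemble(n_residues = 20, sigma = seq(0.1, 0.6, length.out = 20),
                       include_predicted = TRUE, seed = 2)
  pl <- extract_profile(ens$structures$pred, "plddt")
  expect_true(all(pl$value >= 50 & pl$value <= 100))
  bad <- ens$structures$pred
  bad$b[1] <- 150
  expect_error(extract_profile(bad, "plddt"), "\\[0, 100\\]")
  # crystal B-factors inside [0,100] pass when asked for plddt (caller's call)
  expect_silent(extract_profile(s, "plddt"))
})

test_that("both PAE JSON dialects give the same matrix and errors are caught", {
  mat <- rbind(c(0, 3.5), c(4.0, 0))
  pa <- write_pae_dialect_a(withr::local_tempfile(fileext = ".json"), mat)
  pb <- write_pae_dialect_b(withr::local_tempfile(fileext = ".json"), mat)
  expect_equal(read_pae(pa), mat)
  expect_equal(read_pae(pb), mat)
  # ragged rows
  ragged <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"predicted_aligned_error": [[0, 1.5], [2.0]]}]', ragged)
  expect_error(read_pae(ragged), "ragged|square")
  # negative entries
  neg <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"predicted_aligned_error": [[0, -1], [1, 0]]}]', neg)
  expect_error(read_pae(neg), "negative")
  # larger random matrix round-trips through both dialects
  set.seed(9)
  big <- matrix(runif(49, 0, 30), 7, 7); diag(big) <- 0
  expect_equal(read_pae(write_pae_dialect_a(withr::local_tempfile(fileext = ".json"), big)),
               big, tolerance = 1e-12)
  expect_equal(read_pae(write_pae_dialect_b(withr::local_tempfile(fileext = ".json"), big)),
               big, tolerance = 1e-12)
})

test_that("hydrogens, waters and hetero residues are stripped on read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  HA  ALA A   1       0.500   0.000   0.000  1.00 10.00           H",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 10.00           C",
    "HETATM    4  ZN   ZN A 101       9.000   0.000   0.000  1.00 10.00          ZN",
    "HETATM    5  O   HOH A 201      12.000   0.000   0.000  1.00 10.00           O",
    "END"
  ), path)
  s <- read_structure(path)
  expect_equal(nrow(s), 2)
  expect_setequal(s$resid, c("ALA", "GLY"))
})
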