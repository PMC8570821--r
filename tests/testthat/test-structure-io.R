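toy_pdb_text <- c(
  "HEADER    TOY",
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
  "END")

test_that("read_pdb parses fixed-column records verbatim", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text, f)
  s <- read_pdb(f)
  expect_s3_class(s, "Structure")
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$coords,
               rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(s$atoms$atom_name, rep("CA", 3))
  expect_equal(s$atoms$residue_index, 1:3)
})

test_that("read_pdb applies the altloc and water policies", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AALA A   2       3.800   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   2       3.900   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(n_atoms(s), 3L)                       # altloc B + water gone
  expect_equal(s$coords[2, 1], 3.8)                  # altloc A kept
  expect_false(any(s$atoms$residue_name == "HOH"))
})

test_that("read_pdb error contract: missing file, bad coords, empty file", {
  expect_error(read_pdb(file.path(tempdir(), "no-such-file.pdb")),
               "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(toy_pdb_text[1:2],
               "ATOM      2  CA  ALA A   2       3.8xx   0.000   0.000  1.00  0.00           C"),
             f)
  expect_error(read_pdb(f), "line 3")
  writeLines("HEADER    EMPTY", f)
  expect_error(read_pdb(f), "ATOM")
})

test_that("PDB write/read round-trips preserve coordinates to 3 decimals", {
  s <- make_toy(toy_spec(8))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  expect_false(any(grepl("^MODEL", readLines(f))))
  s2 <- read_pdb(f)
  expect_equal(s2$coords, s$coords, tolerance = 6e-4, ignore_attr = TRUE)
  s3 <- read_pdb(write_pdb(s2, f))
  expect_identical(s3$coords, s2$coords)   # quantized coords are a fixed point
})

test_that("multi-model PDB carries a whole ensemble in order", {
  s <- make_toy(toy_spec(6))
  coords <- array(0, c(2, n_atoms(s), 3))
  coords[1, , ] <- s$coords
  coords[2, , ] <- s$coords + 1
  ens <- ensemble(coords)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f, ens)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 2L)
  back <- read_multimodel_pdb(f)
  expect_equal(back$ensemble$coords, ens$coords, tolerance = 5e-4,
               ignore_attr = TRUE)
  # order preserved: model 2 is the shifted copy
  expect_true(all(abs(back$ensemble$coords[2, , ] -
                      back$ensemble$coords[1, , ] - 1) < 5e-4))
  expect_error(write_pdb(make_toy(toy_spec(5)), f, ens), "atoms")
})

test_that("DCD files read back with an independent reader, frames in order", {
  s <- make_toy(toy_spec(6))
  M <- 3L
  coords <- array(0, c(M, n_atoms(s), 3))
  for (i in seq_len(M)) coords[i, , ] <- s$coords + (i - 1) * 0.5
  ens <- ensemble(coords)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(ens, f)
  # header frame count, via the independent bio3d reader
  xyz <- bio3d::read.dcd(f, verbose = FALSE)
  expect_equal(nrow(xyz), M)
  for (i in seq_len(M)) {
    got <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    expect_equal(got, coords[i, , ], tolerance = 1e-5, ignore_attr = TRUE)
  }
  back <- read_dcd_ensemble(f)
  expect_equal(back$coords, coords, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("selection grammar: forms, conjunction, idempotence, order", {
  s <- make_toy(toy_spec(12))
  expect_equal(sum(select_atoms(s, "calpha")), 12L)
  expect_equal(sum(select_atoms(s, "name CB")), 12L)
  expect_equal(sum(select_atoms(s, "chain A and resid 1-5")), 10L)
  expect_equal(sum(select_atoms(s, "calpha and resid 3")), 1L)
  expect_identical(select_atoms(s, "calpha and chain A"),
                   select_atoms(s, "chain A and calpha"))
  expect_identical(select_atoms(s, "calpha and calpha"),
                   select_atoms(s, "calpha"))
  expect_false(any(select_atoms(s, "name XX")))
  expect_error(select_atoms(s, "backbone"), "Supported grammar")
  expect_error(select_atoms(s, "resid one-two"), "Supported grammar")
})

test_that("Structure invariants are enforced", {
  s <- make_toy(toy_spec(5))
  expect_error(Structure(s$atoms[1:2, ], s$coords[1:2, ]), "at least 3")
  bad <- s$coords; bad[1, 1] <- NA
  expect_error(set_coords(s, bad), "non-finite")
  at <- s$atoms; at$atom_name[2] <- "CA"   # duplicates residue 1's CA
  expect_error(Structure(at, s$coords, coarse_grained = TRUE), "duplicate")
  # full-atom structures must have exactly one CA per residue
  at2 <- s$atoms; at2$atom_name[1] <- "CX"
  expect_error(Structure(at2, s$coords, coarse_grained = FALSE), "CA")
})
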