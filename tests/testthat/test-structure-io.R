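minimal_ala_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.161  -4.922  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.339   7.183  -3.882  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      10.527   6.226  -4.119  1.00  0.00           C",
    "TER       6      ALA A   1",
    "END"
  ), path)
  path
}

test_that("a minimal one-residue PDB parses into one chain, one residue, five atoms", {
  f <- minimal_ala_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(f)
  expect_equal(nrow(s), 5L)
  expect_equal(unique(s$chain), "A")
  expect_equal(unique(s$resno), 1L)
  expect_equal(unique(s$resid), "ALA")
  expect_setequal(s$elety, c("N", "CA", "C", "O", "CB"))
  expect_equal(s$element[s$elety == "N"], "N")
})

test_that("write then read is the identity on retained fields, to PDB precision", {
  for (fx in list(make_helix(6)$structure,
                  make_ion_pair(3.4, "ASP", "ARG")$structure,
                  make_ion_pair(4.6, "GLU", "HIS", resno = c(184L, 189L))$structure)) {
    f <- tempfile(fileext = ".pdb")
    write_structure(fx, f)
    back <- read_structure(f)
    expect_equal(nrow(back), nrow(fx))
    expect_identical(back$resno, fx$resno)
    expect_identical(back$resid, fx$resid)
    expect_identical(back$elety, fx$elety)
    expect_identical(back$chain, fx$chain)
    expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                        as.matrix(fx[, c("x", "y", "z")]))), 5e-4 + 1e-9)
  }
})

test_that("author residue numbering is preserved verbatim", {
  fx <- make_ion_pair(3.5, "GLU", "ARG", resno = c(184L, 211L))
  f <- tempfile(fileext = ".pdb")
  write_structure(fx$structure, f)
  lines <- readLines(f)
  expect_true(any(grepl("^ATOM.*GLU A 184", lines)))
  back <- read_structure(f)
  expect_setequal(unique(back$resno), c(184L, 211L))
})

test_that("alternate locations resolve by occupancy or file order", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  BALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  AALA A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), f)
  top <- read_structure(f, altloc_policy = "highest_occupancy")
  expect_equal(nrow(top), 2L)
  expect_equal(top$x[top$elety == "N"], 1.0)
  first <- read_structure(f, altloc_policy = "first")
  expect_equal(first$x[first$elety == "N"], 0.0)
})

test_that("HETATM records and waters are excluded at parse time", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "HETATM    3 ZN    ZN A 201       5.000   5.000   5.000  1.00  0.00          ZN",
    "END"
  ), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 1L)
  expect_equal(s$resid, "ALA")
})

test_that("unreadable and atom-free files are errors", {
  expect_error(read_structure(tempfile()), "does not exist")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1 ZN    ZN A 201       5.0   5.0   5.0  1.00  0.00",
               "END"), f)
  expect_error(read_structure(f), "no ATOM records")
  expect_error(write_structure(make_helix(5)$structure[0, ], tempfile()),
               "empty")
})

test_that("extract_sequence maps residues to one letter each", {
  s <- dplyr::bind_rows(make_residue("GLY", 1), make_residue("ALA", 2))
  expect_equal(extract_sequence(s), "GA")
  ch <- make_random_chain(15, seed = 3)
  expect_equal(nchar(extract_sequence(ch)), 15L)
  mse <- make_residue("ALA", 3)
  mse$resid <- "MSE"
  expect_error(extract_sequence(dplyr::bind_rows(s, mse)), "MSE")
})

test_that("FASTA reading preserves order, uppercases and handles degenerate input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acd", ">b", "WKR", "ty"), f)
  fa <- read_fasta(f)
  expect_equal(fa$header, c("a", "b"))
  expect_equal(fa$sequence, c("ACD", "WKRTY"))

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  bad <- tempfile(fileext = ".fasta")
  writeLines(c("ACDE", ">late"), bad)
  expect_error(read_fasta(bad), "parse")
})
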