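## A 3-residue poly-Ala fragment written in both PDB and mmCIF.
make_pdb_fixture <- function() {
  m <- build_fixture("helix", 4, sequence = "AAAA")
  m$atoms <- m$atoms[m$atoms$resno <= 3, ]
  f <- tempfile(fileext = ".pdb")
  write_model(em_model(m$atoms), f)
  f
}

pdb_to_cif <- function(pdb_path) {
  m <- read_model(pdb_path)
  a <- m$atoms
  f <- tempfile(fileext = ".cif")
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "auth_asym_id", "auth_seq_id",
                                   "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                                   "Cartn_z", "occupancy", "B_iso_or_equiv")))
  rows <- sprintf("ATOM %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
                  seq_len(nrow(a)), a$element, a$atom, a$resid, a$chain,
                  a$resno, ifelse(a$ins == "", "?", a$ins),
                  a$x, a$y, a$z, a$occ, a$b)
  writeLines(c(hdr, rows, "#"), f)
  f
}

test_that("PDB parsing recovers the poly-Ala fixture hierarchy", {
  f <- make_pdb_fixture()
  m <- read_model(f)
  expect_equal(length(unique(m$atoms$resno)), 3)
  ## 5 heavy atoms per Ala residue (N, CA, C, O, CB)
  expect_equal(as.numeric(table(m$atoms$resno)), c(5, 5, 5))
  expect_true(all(m$atoms$element %in% c("C", "N", "O")))
})

test_that("mmCIF parse equals PDB parse of the same content", {
  f <- make_pdb_fixture()
  m_pdb <- read_model(f)
  m_cif <- read_model(pdb_to_cif(f))
  expect_equal(m_cif$atoms$atom, m_pdb$atoms$atom)
  expect_equal(m_cif$atoms$resno, m_pdb$atoms$resno)
  expect_equal(coords(m_cif), coords(m_pdb), tolerance = 1e-6)
})

test_that("HETATM-only files give one chain of waters", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2      13.000  10.000  10.000  1.00  0.00           O",
    "END"), f)
  m <- read_model(f)
  expect_equal(unique(m$atoms$resid), "HOH")
  expect_equal(length(unique(m$atoms$chain)), 1)
  expect_equal(nrow(m$atoms), 2)
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70 10.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       6.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  m <- read_model(f)
  expect_equal(nrow(m$atoms), 2)
  ## CA: keep B (occ 0.7); CB: tie, keep first (A)
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 5)
  expect_equal(m$atoms$x[m$atoms$atom == "CB"], 1)
})

test_that("insertion codes are part of residue identity", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  10       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A  10A      3.800   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- read_model(f)
  expect_equal(nrow(m$atoms), 2)
  expect_setequal(m$atoms$ins, c("", "A"))
})

test_that("unparsable and empty files raise errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_model(f), "no atom records")
  f2 <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1       x.xxx   0.000   0.000", f2)
  expect_error(read_model(f2), "coordinate")
})

test_that("model round-trip via PDB preserves scored quantities", {
  m <- build_fixture("helix", 6)
  f <- tempfile(fileext = ".pdb")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$atoms$atom, m$atoms$atom)
  expect_equal(coords(back), coords(m), tolerance = 1e-3)
  expect_equal(back$atoms$occ, m$atoms$occ)
  expect_equal(back$atoms$b, m$atoms$b)
})

test_that("normalization strips H, zeroes B, resets all-zero occupancies", {
  a <- build_fixture("helix", 4)$atoms
  a$b <- 25
  h <- a[1, ]; h$atom <- "H"; h$element <- "H"; h$x <- h$x + 0.5
  m <- em_model(rbind(a, h))
  norm <- normalize_for_scoring(m)
  expect_equal(nrow(norm$atoms), nrow(a))
  expect_true(all(norm$atoms$b == 0))
  expect_true(all(!norm$atoms$is_h))
  ## untouched input
  expect_true(all(m$atoms$b == 25))
  ## all-zero occupancy reset
  a0 <- a; a0$occ <- 0
  expect_true(all(normalize_for_scoring(em_model(a0))$atoms$occ == 1))
  ## mixed occupancies unchanged
  am <- a; am$occ <- rep(c(0.5, 1), length.out = nrow(am))
  expect_equal(sort(unique(normalize_for_scoring(em_model(am))$atoms$occ)),
               c(0.5, 1))
})
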