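test_that("PDB round-trip preserves coordinates to format precision and labels exactly", {
  fab <- build_toy_fab(toy_fab_spec(seed = 5))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fab$atoms, tmp)
  back <- read_structure(tmp)
  expect_equal(nrow(back), nrow(fab$atoms))
  expect_equal(back$chain_id, fab$atoms$chain_id)
  expect_equal(back$residue_number, fab$atoms$residue_number)
  expect_equal(back$residue_name, fab$atoms$residue_name)
  expect_equal(back$atom_name, fab$atoms$atom_name)
  for (col in c("x", "y", "z")) {
    expect_lt(max(abs(back[[col]] - fab$atoms[[col]])), 5.1e-4)
  }
})

test_that("altloc records resolve to highest occupancy with ties by file order", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CB AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "ATOM      6  O   ALA A   1       3.000   0.000   0.000  0.00  0.00           O",
    "END"
  ), tmp)
  atoms <- read_structure(tmp)
  expect_equal(nrow(atoms), 3) # zero-occupancy O dropped, one CA, one CB
  expect_equal(atoms$x[atoms$atom_name == "CA"], 1.0) # highest occupancy wins
  expect_equal(atoms$x[atoms$atom_name == "CB"], 2.0) # tie -> first in file
})

test_that("space group and SEQRES metadata are scanned from the header", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   37.670   69.730   89.850  99.71 101.43 105.66 P 1           1",
    "SEQRES   1 A    4  MET GLY LYS ASP",
    "ATOM      1  CA  MET A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"
  ), tmp)
  atoms <- read_structure(tmp)
  expect_equal(attr(atoms, "space_group"), "P 1")
  expect_equal(attr(atoms, "seqres")$A, "MGKD")
})

test_that("atom table invariants are enforced", {
  df <- data.frame(element = "C", atom_name = "CA", residue_name = "ALA",
                   residue_number = 1, chain_id = "A", x = 0, y = 0, z = 0)
  expect_s3_class(as_atomset(df), "fab_atoms")
  expect_error(as_atomset(rbind(df, df)), "duplicated")
  bad <- df; bad$x <- Inf
  expect_error(as_atomset(bad), "finite")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("annotate_fab applies default and overridden boundaries and is idempotent", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 130, seed = 2))
  ann <- annotate_fab(fab$atoms, heavy = "H", light = "L")
  expect_equal(ann$domain_ranges$VH, c(1L, 117L))
  expect_equal(ann$domain_ranges$VL, c(1L, 109L))
  expect_equal(ann$domain_ranges$CH1[1], 118L)
  expect_equal(ann$domain_ranges$CL[1], 110L)
  over <- annotate_fab(fab$atoms, heavy = "H", light = "L",
                       boundaries = list(VH = c(1, 120)))
  expect_equal(over$domain_ranges$CH1[1], 121L)
  again <- annotate_fab(over, heavy = "H", light = "L",
                        boundaries = list(VH = c(1, 120)))
  expect_identical(again$domain_ranges, over$domain_ranges)
  expect_identical(again$atoms$residue_number, over$atoms$residue_number)
  expect_error(annotate_fab(fab$atoms, heavy = "H", light = "Z"), "chain 'Z'")
  expect_error(annotate_fab(fab$atoms, heavy = "H", light = "L",
                            boundaries = list(VH = c(500, 600))), "outside observed")
})

test_that("detect_gaps reports one gap of the deleted size for interior deletions", {
  for (k in 1:10) {
    res <- setdiff(1:60, seq(25, length.out = k))
    atoms <- atoms_fixture("C", "A", res,
                           cbind(3.8 * res, 0, 0))
    g <- detect_gaps(atoms)
    expect_equal(nrow(g), 1)
    expect_equal(g$n_missing, k)
    expect_equal(g$last_before, 24)
    expect_equal(g$first_after, 25 + k)
  }
  contiguous <- atoms_fixture("C", "A", 1:100, cbind(3.8 * (1:100), 0, 0))
  expect_equal(nrow(detect_gaps(contiguous)), 0)
})

test_that("multiple gaps and C-terminal truncations are accounted separately", {
  res <- c(1:10, 12:20, 25:30)
  atoms <- atoms_fixture("C", "A", res, cbind(3.8 * res, 0, 0))
  g <- detect_gaps(atoms)
  expect_equal(nrow(g), 2)
  expect_equal(g$n_missing, c(1L, 4L))
  # full-sequence record longer than the last observed residue
  hexa <- build_synthetic_crystal_form("hexagonal")
  gh <- detect_gaps(hexa)
  cterm <- gh[gh$kind == "c_terminal", ]
  expect_equal(cterm$n_missing, 11L)
  expect_equal(cterm$last_before, 217L)
})

test_that("insertion codes adjacent to a gap flag it as numbering-ambiguous", {
  atoms <- as_atomset(data.frame(
    element = "C", atom_name = "CA", residue_name = "ALA",
    residue_number = c(1, 2, 2, 6, 7),
    insertion_code = c("", "", "A", "", ""),
    chain_id = "A", x = (1:5) * 3.8, y = 0, z = 0
  ))
  g <- detect_gaps(atoms)
  expect_equal(nrow(g), 1)
  expect_true(g$ambiguous)
})

test_that("count_span_residues counts inclusively and rejects reversed spans", {
  expect_equal(count_span_residues("K218", "A228"), 11L)
  expect_equal(count_span_residues("S132", "T135"), 4L)
  expect_equal(count_span_residues("X5", "X5"), 1L)
  expect_error(count_span_residues("A10", "A5"), "precedes")
})

test_that("formal charge follows the protonation threshold rule", {
  pep <- atoms_fixture("C", "A", 1:2, cbind(c(0, 3.8), 0, 0),
                       resname = c("LYS", "ASP"))
  expect_equal(total_formal_charge(pep, 7, blocked_termini = TRUE)$charge, 0L)
  expect_equal(total_formal_charge(pep, 2, blocked_termini = TRUE)$charge, 1L)
  his <- atoms_fixture("C", "A", 1:3, cbind(c(0, 3.8, 7.6), 0, 0), resname = "HIS")
  expect_equal(total_formal_charge(his, 7, blocked_termini = TRUE)$charge, 0L)
  expect_equal(total_formal_charge(his, 5, blocked_termini = TRUE)$charge, 3L)
  # free termini contribute +1/-1 at neutral pH
  gly <- atoms_fixture("C", "A", 1:2, cbind(c(0, 3.8), 0, 0), resname = "GLY")
  expect_equal(total_formal_charge(gly, 7)$charge, 0L)
})

test_that("total formal charge is monotonically non-increasing in pH", {
  fab <- build_toy_fab(toy_fab_spec(seed = 9))
  charges <- vapply(seq(1, 13, by = 0.5),
                    function(p) total_formal_charge(fab, p)$charge, integer(1))
  expect_true(all(diff(charges) <= 0))
})

test_that("nonstandard residues are excluded with a warning list", {
  pep <- atoms_fixture("C", "A", 1:2, cbind(c(0, 3.8), 0, 0),
                       resname = c("LYS", "MSE"))
  expect_warning(res <- total_formal_charge(pep, 7, blocked_termini = TRUE),
                 "MSE")
  expect_equal(res$skipped[[1]], "MSE")
  expect_equal(res$charge, 1L)
})
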