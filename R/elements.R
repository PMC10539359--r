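# Element and residue reference data used across SASA, Rg and SAXS calculations.

# atomic number (= electron count for neutral atoms) and mass for the elements
# that occur in protein structures and common ligands/ions
element_table <- function() {
  tibble::tribble(
    ~element, ~atomic_number, ~mass,
    "H",  1L,  1.008,
    "C",  6L, 12.011,
    "N",  7L, 14.007,
    "O",  8L, 15.999,
    "NA", 11L, 22.990,
    "MG", 12L, 24.305,
    "P", 15L, 30.974,
    "S", 16L, 32.06,
    "CL", 17L, 35.45,
    "K", 19L, 39.098,
    "CA", 20L, 40.078,
    "MN", 25L, 54.938,
    "FE", 26L, 55.845,
    "ZN", 30L, 65.38,
    "SE", 34L, 78.971
  )
}

element_mass <- function(element) {
  tab <- element_table()
  m <- tab$mass[match(toupper(element), tab$element)]
  unknown <- unique(element[is.na(m)])
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  m
}

# as element_mass, but unknown elements fall back to carbon's mass with a
# warning instead of an error (rare ligand atoms should not break reading)
element_mass_or_default <- function(element) {
  tab <- element_table()
  m <- tab$mass[match(toupper(element), tab$element)]
  unknown <- unique(element[is.na(m)])
  if (length(unknown) > 0) {
    warn(paste0("unknown element(s) assigned carbon mass: ",
                paste(unknown, collapse = ", ")))
    m[is.na(m)] <- 12.011
  }
  m
}

element_electrons <- function(element) {
  tab <- element_table()
  z <- tab$atomic_number[match(toupper(element), tab$element)]
  unknown <- unique(element[is.na(z)])
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  as.numeric(z)
}

# in-chain residue formulas (amino acid minus one water); columns C,H,N,O,S
residue_formula_table <- function() {
  tibble::tribble(
    ~residue_name, ~C, ~H, ~N, ~O, ~S,
    "GLY",  2L,  3L, 1L, 1L, 0L,
    "ALA",  3L,  5L, 1L, 1L, 0L,
    "SER",  3L,  5L, 1L, 2L, 0L,
    "PRO",  5L,  7L, 1L, 1L, 0L,
    "VAL",  5L,  9L, 1L, 1L, 0L,
    "THR",  4L,  7L, 1L, 2L, 0L,
    "CYS",  3L,  5L, 1L, 1L, 1L,
    "LEU",  6L, 11L, 1L, 1L, 0L,
    "ILE",  6L, 11L, 1L, 1L, 0L,
    "ASN",  4L,  6L, 2L, 2L, 0L,
    "ASP",  4L,  5L, 1L, 3L, 0L,
    "GLN",  5L,  8L, 2L, 2L, 0L,
    "LYS",  6L, 12L, 2L, 1L, 0L,
    "GLU",  5L,  7L, 1L, 3L, 0L,
    "MET",  5L,  9L, 1L, 1L, 1L,
    "HIS",  6L,  7L, 3L, 1L, 0L,
    "PHE",  9L,  9L, 1L, 1L, 0L,
    "ARG",  6L, 12L, 4L, 1L, 0L,
    "TYR",  9L,  9L, 1L, 2L, 0L,
    "TRP", 11L, 10L, 2L, 1L, 0L
  )
}

# electrons per in-chain residue, used for residue-level coarse-grained SAXS
residue_electrons <- function(residue_name) {
  tab <- residue_formula_table()
  i <- match(toupper(residue_name), tab$residue_name)
  e <- 6 * tab$C[i] + 1 * tab$H[i] + 7 * tab$N[i] + 8 * tab$O[i] + 16 * tab$S[i]
  # unknown residues fall back to the mean residue electron count
  e[is.na(e)] <- round(mean(6 * tab$C + tab$H + 7 * tab$N + 8 * tab$O + 16 * tab$S))
  as.numeric(e)
}

aa_three_to_one <- function(residue_name) {
  map <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V"
  )
  out <- unname(map[toupper(residue_name)])
  out[is.na(out)] <- "X"
  out
}
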