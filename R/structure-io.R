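#' Read an atomic structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM records into a tidy atom table, one row per atom.
#' Alternate locations are resolved to the highest-occupancy conformer (ties
#' broken by file order) and zero-occupancy atoms are dropped. When the file
#' carries them, the crystallographic space group (CRYST1) and the full
#' per-chain sequence (SEQRES) are attached as attributes so that downstream
#' gap detection can compare observed residues against the deposited sequence.
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"` (default, by file extension), `"pdb"` or
#'   `"mmcif"`.
#' @param multi Read all models of a multi-model file? If `FALSE` (default)
#'   only the first model is returned.
#'
#' @return A tibble of class `fab_atoms` with columns `atom_id`, `element`,
#'   `atom_name`, `residue_name`, `residue_number`, `insertion_code`,
#'   `chain_id`, `x`, `y`, `z` (Angstrom), `occupancy`, `b_factor`, `mass`,
#'   `is_het`, plus attributes `space_group` (character or `NA`) and `seqres`
#'   (named list of one-letter sequences, possibly empty). With `multi = TRUE`
#'   a list with elements `topology` (the first-model atom table) and `frames`
#'   (list of N x 3 coordinate matrices).
#' @examples
#' fab <- build_toy_fab(toy_fab_spec(seed = 1))
#' tmp <- tempfile(fileext = ".pdb")
#' write_structure(fab$atoms, tmp)
#' atoms <- read_structure(tmp)
#' nrow(atoms)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), multi = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = multi, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = multi, verbose = FALSE)
    },
    error = function(e) abort(paste0("failed to parse ", format, " file '", path, "': ",
                                     conditionMessage(e)))
  )
  atoms <- atoms_from_bio3d(pdb)
  if (nrow(atoms) == 0) abort(paste0("no atoms with positive occupancy in ", path))
  attr(atoms, "space_group") <- scan_space_group(path, format)
  attr(atoms, "seqres") <- if (format == "pdb") scan_seqres(path) else list()
  class(atoms) <- c("fab_atoms", class(atoms))
  if (multi) {
    nxyz <- ncol(pdb$xyz)
    keep <- attr(atoms, "kept_rows")
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
      m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
      m[keep, , drop = FALSE]
    })
    attr(atoms, "kept_rows") <- NULL
    return(list(topology = atoms, frames = frames))
  }
  attr(atoms, "kept_rows") <- NULL
  atoms
}

# convert a bio3d pdb object to the tidy atom table, resolving altlocs
atoms_from_bio3d <- function(pdb) {
  a <- tibble::as_tibble(pdb$atom)
  a$row0 <- seq_len(nrow(a))
  a$insert[is.na(a$insert) | a$insert == " "] <- ""
  a$alt[is.na(a$alt) | a$alt == " "] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  a <- dplyr::filter(a, .data$o > 0)
  # altloc resolution: keep the highest-occupancy conformer, ties by file order
  a <- a |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$row0, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$row0)
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- bio3d::atom2ele(a$elety)
  } else {
    miss <- is.na(elesy) | trimws(elesy) == ""
    if (any(miss)) elesy[miss] <- bio3d::atom2ele(a$elety[miss])
  }
  elesy <- toupper(trimws(elesy))
  out <- tibble::tibble(
    atom_id = as.integer(a$eleno),
    element = elesy,
    atom_name = a$elety,
    residue_name = a$resid,
    residue_number = as.integer(a$resno),
    insertion_code = a$insert,
    chain_id = as.character(a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = a$o,
    b_factor = a$b,
    mass = element_mass_or_default(elesy),
    is_het = a$type == "HETATM"
  )
  attr(out, "kept_rows") <- a$row0
  out
}

scan_space_group <- function(path, format) {
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    cry <- lines[startsWith(lines, "CRYST1")]
    if (length(cry) == 0) return(NA_character_)
    sg <- trimws(substr(cry[1], 56, 66))
    if (nzchar(sg)) sg else NA_character_
  } else {
    lines <- readLines(path, warn = FALSE)
    hit <- grep("_symmetry\\.space_group_name_H-M", lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sg <- sub(".*_symmetry\\.space_group_name_H-M\\s+", "", hit[1])
    sg <- gsub("['\"]", "", trimws(sg))
    if (nzchar(sg)) sg else NA_character_
  }
}

# SEQRES records -> named list of one-letter sequences
scan_seqres <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sq <- lines[startsWith(lines, "SEQRES")]
  if (length(sq) == 0) return(list())
  chain <- substr(sq, 12, 12)
  out <- list()
  for (ch in unique(chain)) {
    res3 <- unlist(strsplit(trimws(substr(sq[chain == ch], 20, 80)), "\\s+"))
    out[[ch]] <- paste(aa_three_to_one(res3), collapse = "")
  }
  out
}

#' Write an atom table (or trajectory) as PDB
#'
#' Coordinates are written at the PDB format's 3-decimal precision. A list of
#' coordinate frames produces a multi-model PDB.
#'
#' @param atoms An atom table as returned by [read_structure()].
#' @param path Output file path.
#' @param frames Optional list of N x 3 coordinate matrices; when given, a
#'   multi-model PDB is written using `atoms` as the topology.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, frames = NULL) {
  atoms <- validate_atoms(atoms)
  if (is.null(frames)) {
    xyz <- as.vector(t(coords_matrix(atoms)))
  } else {
    xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  }
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(atoms$is_het, "HETATM", "ATOM"),
    resno = atoms$residue_number,
    resid = atoms$residue_name,
    eleno = atoms$atom_id,
    elety = atoms$atom_name,
    chain = atoms$chain_id,
    insert = ifelse(atoms$insertion_code == "", NA, atoms$insertion_code),
    o = atoms$occupancy,
    b = atoms$b_factor,
    elesy = atoms$element
  )
  invisible(path)
}

#' Construct/validate a tidy atom table
#'
#' Checks the atom-table invariants: finite coordinates, positive masses and
#' uniqueness of (chain, residue number, insertion code, atom name).
#'
#' @param df A data frame with the columns described in [read_structure()].
#'   Missing bookkeeping columns (`occupancy`, `b_factor`, `insertion_code`,
#'   `is_het`, `atom_id`, `mass`) are filled with defaults; `mass` is derived
#'   from `element` when absent.
#' @return A validated `fab_atoms` tibble.
#' @export
as_atomset <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("atom table missing columns: ", paste(miss, collapse = ", ")))
  if (!"atom_id" %in% names(df)) df$atom_id <- seq_len(nrow(df))
  if (!"insertion_code" %in% names(df)) df$insertion_code <- ""
  if (!"occupancy" %in% names(df)) df$occupancy <- 1
  if (!"b_factor" %in% names(df)) df$b_factor <- 0
  if (!"is_het" %in% names(df)) df$is_het <- FALSE
  if (!"mass" %in% names(df)) df$mass <- element_mass(df$element)
  df$residue_number <- as.integer(df$residue_number)
  out <- df[, c("atom_id", "element", "atom_name", "residue_name", "residue_number",
                "insertion_code", "chain_id", "x", "y", "z", "occupancy",
                "b_factor", "mass", "is_het")]
  class(out) <- c("fab_atoms", class(out))
  validate_atoms(out)
}

validate_atoms <- function(atoms) {
  if (nrow(atoms) == 0) abort("empty atom table")
  xyz <- coords_matrix(atoms)
  if (!all(is.finite(xyz))) abort("non-finite coordinates in atom table")
  if (any(!is.finite(atoms$mass) | atoms$mass <= 0)) abort("all atom masses must be > 0")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code, atoms$atom_name)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated atom identity: ", key[duplicated(key)][1]))
  }
  atoms
}

# protein atoms only (drop waters/heteroatoms) -- the default for analyses
protein_atoms <- function(atoms, include_hetero = FALSE) {
  if (include_hetero) return(atoms)
  dplyr::filter(atoms, !.data$is_het, .data$residue_name != "HOH")
}

# Calpha subset of a chain/range, ordered by residue number then insertion code
ca_atoms <- function(atoms, chain = NULL, range = NULL) {
  out <- dplyr::filter(protein_atoms(atoms), .data$atom_name == "CA")
  if (!is.null(chain)) out <- dplyr::filter(out, .data$chain_id %in% chain)
  if (!is.null(range)) {
    out <- dplyr::filter(out, .data$residue_number >= range[1],
                         .data$residue_number <= range[2])
  }
  dplyr::arrange(out, .data$chain_id, .data$residue_number, .data$insertion_code)
}
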