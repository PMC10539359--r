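#' Detect unresolved loops (gaps) in a structure
#'
#' Scans each protein chain for jumps in consecutive observed residue numbers.
#' A jump of more than one between neighbouring observed residues yields one
#' gap record. When the file provided a full-sequence record (SEQRES), the
#' missing one-letter sequence is filled in and C-terminal truncations (full
#' sequence longer than the last observed residue) are reported as separate
#' records with `kind = "c_terminal"`.
#'
#' @param fab A `fab_structure` or an atom table.
#' @return A tibble with columns `chain_id`, `kind` (`"internal"` or
#'   `"c_terminal"`), `last_before`, `first_after`, `n_missing`,
#'   `missing_sequence` (NA when no full-sequence record exists) and
#'   `ambiguous` (TRUE when insertion codes inside the gap region make the
#'   numbering-based count unreliable).
#' @examples
#' fab <- build_synthetic_crystal_form("hexagonal")
#' detect_gaps(fab)
#' @export
detect_gaps <- function(fab) {
  atoms <- if (inherits(fab, "fab_structure")) fab$atoms else fab
  seqres <- attr(atoms, "seqres") %||% list()
  ca <- ca_atoms(atoms)
  out <- list()
  for (ch in unique(ca$chain_id)) {
    cc <- dplyr::filter(ca, .data$chain_id == ch)
    res <- cc$residue_number
    ins <- cc$insertion_code
    jump <- which(diff(res) > 1)
    for (j in jump) {
      n_missing <- res[j + 1] - res[j] - 1L
      # insertion codes flanking the putative gap make pure-number counting unsafe
      ambiguous <- nzchar(ins[j]) || nzchar(ins[j + 1])
      missing_seq <- NA_character_
      if (!is.null(seqres[[ch]]) && !ambiguous &&
          res[j + 1] - 1L <= nchar(seqres[[ch]]) && res[j] + 1L >= 1L) {
        missing_seq <- substr(seqres[[ch]], res[j] + 1L, res[j + 1] - 1L)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chain_id = ch, kind = "internal",
        last_before = res[j], first_after = res[j + 1],
        n_missing = n_missing, missing_sequence = missing_seq,
        ambiguous = ambiguous
      )
    }
    if (!is.null(seqres[[ch]])) {
      full_len <- nchar(seqres[[ch]])
      last_obs <- max(res)
      if (full_len > last_obs) {
        out[[length(out) + 1]] <- tibble::tibble(
          chain_id = ch, kind = "c_terminal",
          last_before = last_obs, first_after = full_len + 1L,
          n_missing = full_len - last_obs,
          missing_sequence = substr(seqres[[ch]], last_obs + 1L, full_len),
          ambiguous = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chain_id = character(), kind = character(), last_before = integer(),
      first_after = integer(), n_missing = integer(),
      missing_sequence = character(), ambiguous = logical()
    ))
  }
  dplyr::bind_rows(out)
}

#' Count residues in an inclusive span
#'
#' Residue specs are either plain numbers or labels such as `"K218"` (a
#' one-letter residue type followed by the residue number); the count is
#' `end - start + 1`.
#'
#' @param start_label,end_label Residue specs (e.g. `"K218"`, `"A228"`, `218`).
#' @return Integer count of residues in the span.
#' @examples
#' count_span_residues("K218", "A228") # 11
#' @export
count_span_residues <- function(start_label, end_label) {
  s <- parse_residue_spec(start_label)
  e <- parse_residue_spec(end_label)
  if (e < s) abort(paste0("span end (", e, ") precedes start (", s, ")"))
  as.integer(e - s + 1L)
}

parse_residue_spec <- function(label) {
  if (is.numeric(label)) return(as.integer(label))
  m <- regmatches(label, regexpr("-?[0-9]+", label))
  if (length(m) == 0) abort(paste0("cannot parse residue spec: '", label, "'"))
  as.integer(m)
}
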