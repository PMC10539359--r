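#' Model pKa table for formal-charge bookkeeping
#'
#' A null model assigning every ionisable group its textbook model pKa,
#' independent of structural environment. Each group is protonated iff
#' pH < pKa; the deprotonated state of an acid carries -1 and the protonated
#' state of a base +1.
#'
#' @return A tibble with columns `group` (residue three-letter code or
#'   `"NTERM"`/`"CTERM"`), `pka` and `kind` (`"acid"`/`"base"`).
#' @export
model_pka_table <- function() {
  tibble::tribble(
    ~group,  ~pka, ~kind,
    "ASP",    3.8, "acid",
    "GLU",    4.2, "acid",
    "CYS",    8.3, "acid",
    "TYR",   10.1, "acid",
    "HIS",    6.0, "base",
    "LYS",   10.5, "base",
    "ARG",   12.5, "base",
    "NTERM",  8.0, "base",
    "CTERM",  3.1, "acid"
  )
}

#' Total formal charge of a structure at a given pH
#'
#' Sums the majority protonation state of every ionisable group: a group is
#' protonated iff `pH < pKa`; protonated bases contribute +1, deprotonated
#' acids -1, all other states 0. Chain termini are included unless blocked.
#' This is a sequence-level null model -- it ignores the structural
#' environment of each group, so it is not expected to match structure-based
#' pKa predictions, especially at extreme pH.
#'
#' @param fab A `fab_structure` or atom table.
#' @param pH Solution pH.
#' @param pka A pKa table as from [model_pka_table()].
#' @param blocked_termini Exclude the N-/C-terminal groups of each chain?
#' @return A one-row tibble: `pH`, `charge` (integer), `n_ionisable`, and a
#'   list-column `skipped` of nonstandard residue names excluded with a
#'   warning.
#' @examples
#' fab <- build_toy_fab(toy_fab_spec(seed = 1))
#' total_formal_charge(fab, pH = 7)
#' @export
total_formal_charge <- function(fab, pH, pka = model_pka_table(),
                                blocked_termini = FALSE) {
  stop_if_not_scalar(pH, "pH")
  atoms <- if (inherits(fab, "fab_structure")) fab$atoms else fab
  ca <- ca_atoms(atoms)
  if (nrow(ca) == 0) abort("no protein residues found")
  standard <- residue_formula_table()$residue_name
  skipped <- sort(unique(ca$residue_name[!ca$residue_name %in% standard]))
  if (length(skipped) > 0) {
    warn(paste0("excluding nonstandard residue(s): ", paste(skipped, collapse = ", ")))
  }
  res <- dplyr::filter(ca, .data$residue_name %in% standard)
  groups <- res$residue_name
  if (!blocked_termini) {
    groups <- c(groups, rep(c("NTERM", "CTERM"), each = length(unique(res$chain_id))))
  }
  tab <- dplyr::filter(pka, .data$group %in% groups)
  counts <- table(factor(groups, levels = tab$group))
  protonated <- pH < tab$pka
  q_per <- ifelse(tab$kind == "base", as.numeric(protonated), -as.numeric(!protonated))
  charge <- sum(as.numeric(counts) * q_per)
  tibble::tibble(
    pH = pH, charge = as.integer(round(charge)),
    n_ionisable = sum(as.numeric(counts)),
    skipped = list(skipped)
  )
}
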