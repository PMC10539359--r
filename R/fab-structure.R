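#' Annotate a Fab structure with chain roles and domain boundaries
#'
#' Assigns heavy/light chain roles and the four immunoglobulin domain ranges.
#' The default boundaries follow the usual Fab convention: the light-chain
#' variable domain (VL) spans residues 1-109 and the heavy-chain variable
#' domain (VH) residues 1-117; the constant domains (CL, CH1) are the
#' remainder of each chain.
#'
#' @param atoms An atom table from [read_structure()] or [as_atomset()].
#' @param heavy,light Chain identifiers of the heavy and light chain.
#' @param boundaries Optional named list overriding any of `VH`, `VL`, `CH1`,
#'   `CL` with `c(first, last)` residue numbers (inclusive).
#' @return A `fab_structure` object: a list with `atoms`, `heavy_chain`,
#'   `light_chain` and `domain_ranges` (named list of inclusive ranges).
#' @examples
#' fab <- build_toy_fab(toy_fab_spec(seed = 1))
#' fab2 <- annotate_fab(fab$atoms, heavy = "H", light = "L",
#'                      boundaries = fab$domain_ranges)
#' glance(fab2)
#' @export
annotate_fab <- function(atoms, heavy = "H", light = "L", boundaries = NULL) {
  if (inherits(atoms, "fab_structure")) atoms <- atoms$atoms
  sg <- attr(atoms, "space_group")
  sq <- attr(atoms, "seqres")
  atoms <- validate_atoms(tibble::as_tibble(atoms))
  class(atoms) <- c("fab_atoms", class(atoms))
  attr(atoms, "space_group") <- sg
  attr(atoms, "seqres") <- sq
  for (ch in c(heavy, light)) {
    ca <- ca_atoms(atoms, chain = ch)
    if (nrow(ca) == 0) abort(paste0("chain '", ch, "' absent or has no Calpha atoms"))
  }
  obs_h <- range(ca_atoms(atoms, chain = heavy)$residue_number)
  obs_l <- range(ca_atoms(atoms, chain = light)$residue_number)
  ranges <- list(
    VH = c(1L, 117L), VL = c(1L, 109L),
    CH1 = c(118L, obs_h[2]), CL = c(110L, obs_l[2])
  )
  if (!is.null(boundaries)) {
    bad <- setdiff(names(boundaries), c("VH", "VL", "CH1", "CL"))
    if (length(bad) > 0) abort(paste0("unknown domain name(s): ", paste(bad, collapse = ", ")))
    for (nm in names(boundaries)) ranges[[nm]] <- as.integer(boundaries[[nm]])
    # constant domains follow the variable boundary unless given explicitly
    if ("VH" %in% names(boundaries) && !"CH1" %in% names(boundaries)) {
      ranges$CH1 <- c(ranges$VH[2] + 1L, obs_h[2])
    }
    if ("VL" %in% names(boundaries) && !"CL" %in% names(boundaries)) {
      ranges$CL <- c(ranges$VL[2] + 1L, obs_l[2])
    }
  }
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    obs <- if (nm %in% c("VH", "CH1")) obs_h else obs_l
    if (r[1] > r[2]) abort(paste0(nm, " range is empty: ", r[1], "-", r[2]))
    if (r[1] > obs[2] || r[2] < obs[1]) {
      abort(paste0(nm, " boundary ", r[1], "-", r[2],
                   " lies outside observed residues ", obs[1], "-", obs[2]))
    }
  }
  if (ranges$VH[2] >= ranges$CH1[1]) abort("VH and CH1 ranges overlap")
  if (ranges$VL[2] >= ranges$CL[1]) abort("VL and CL ranges overlap")
  structure(
    list(atoms = atoms, heavy_chain = heavy, light_chain = light,
         domain_ranges = ranges),
    class = "fab_structure"
  )
}

#' @export
print.fab_structure <- function(x, ...) {
  cat("<fab_structure>", nrow(x$atoms), "atoms\n")
  cat("  heavy chain:", x$heavy_chain, " light chain:", x$light_chain, "\n")
  for (nm in names(x$domain_ranges)) {
    r <- x$domain_ranges[[nm]]
    cat(sprintf("  %-4s %d-%d\n", nm, r[1], r[2]))
  }
  invisible(x)
}

domain_chain <- function(fab, domain) {
  if (domain %in% c("VH", "CH1")) fab$heavy_chain else fab$light_chain
}

# Calpha atoms of one annotated domain
domain_ca <- function(fab, domain) {
  ca_atoms(fab$atoms, chain = domain_chain(fab, domain),
           range = fab$domain_ranges[[domain]])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-domain composition of a Fab structure
#'
#' @param x A `fab_structure`.
#' @param ... Unused.
#' @return A tibble with one row per domain: chain, boundaries, residue and
#'   atom counts.
#' @method tidy fab_structure
#' @export
tidy.fab_structure <- function(x, ...) {
  purrr::map_dfr(names(x$domain_ranges), function(nm) {
    r <- x$domain_ranges[[nm]]
    ca <- domain_ca(x, nm)
    tibble::tibble(
      domain = nm,
      chain_id = domain_chain(x, nm),
      first_residue = r[1], last_residue = r[2],
      n_residues_observed = nrow(ca)
    )
  })
}

#' One-row summary of a Fab structure
#'
#' @param x A `fab_structure`.
#' @param ... Unused.
#' @return A one-row tibble: atom counts, chain ids, space group when known.
#' @method glance fab_structure
#' @export
glance.fab_structure <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$atoms),
    n_chains = length(unique(x$atoms$chain_id)),
    heavy_chain = x$heavy_chain,
    light_chain = x$light_chain,
    space_group = attr(x$atoms, "space_group") %||% NA_character_
  )
}
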