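#' Debye-equation SAXS profile from coordinates
#'
#' Computes the orientation-averaged vacuum scattering intensity
#' `I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij)` with constant form factors:
#' the electron count of each atom (`mode = "atomic"`) or of each residue
#' placed at its Calpha (`mode = "residue_cg"`). Pair distances may be binned
#' into a histogram of width `bin_width` for speed; `bin_width = 0` keeps the
#' exact double sum. No excluded-volume or hydration-shell terms are applied.
#'
#' @param atoms Atom table or `fab_structure`.
#' @param q_grid Scattering vector grid in inverse Angstrom (non-negative,
#'   strictly increasing).
#' @param mode `"atomic"` or `"residue_cg"`.
#' @param bin_width Distance histogram bin width in Angstrom (0 = exact).
#' @param coords Optional N x 3 coordinate override (full atom table rows).
#' @return A `fab_saxs_profile` tibble: `q`, `intensity`; attributes `mode`,
#'   `bin_width`, `total_f` (sum of form factors).
#' @examples
#' two <- as_atomset(data.frame(element = "C", atom_name = "C",
#'   residue_name = "UNK", residue_number = 1:2, chain_id = "A",
#'   x = c(0, 10), y = 0, z = 0))
#' debye_profile(two, q_grid = c(0, 0.1), bin_width = 0)
#' @export
debye_profile <- function(atoms, q_grid, mode = c("atomic", "residue_cg"),
                          bin_width = 0.5, coords = NULL) {
  mode <- match.arg(mode)
  if (inherits(atoms, "fab_structure")) atoms <- atoms$atoms
  if (!is.null(coords)) atoms <- set_coords(atoms, as.matrix(coords))
  atoms <- protein_atoms(atoms)
  if (bin_width < 0) abort("bin_width must be >= 0")
  q <- as.numeric(q_grid)
  if (length(q) < 1 || any(q < 0) || any(diff(q) <= 0)) {
    abort("q_grid must be non-negative and strictly increasing")
  }
  if (mode == "atomic") {
    xyz <- coords_matrix(atoms)
    f <- element_electrons(atoms$element)
  } else {
    ca <- dplyr::filter(atoms, .data$atom_name == "CA")
    if (nrow(ca) == 0) abort("residue_cg mode requires Calpha atoms")
    xyz <- coords_matrix(ca)
    f <- residue_electrons(ca$residue_name)
  }
  n <- nrow(xyz)
  if (n < 2) abort("need at least 2 scattering centers")
  d <- as.vector(stats::dist(xyz))
  # pairwise form-factor products in dist() order (lower triangle, by column)
  fp <- tcrossprod(f)[lower.tri(matrix(0, n, n))]
  self_term <- sum(f^2)
  sinc <- function(x) ifelse(x < 1e-12, 1, sin(x) / x)
  if (bin_width == 0) {
    inten <- vapply(q, function(qi) self_term + 2 * sum(fp * sinc(qi * d)),
                    numeric(1))
  } else {
    idx <- pmax(1L, ceiling(d / bin_width))
    w <- rowsum(fp, idx)
    r_mid <- (as.numeric(rownames(w)) - 0.5) * bin_width
    w <- as.vector(w)
    inten <- vapply(q, function(qi) self_term + 2 * sum(w * sinc(qi * r_mid)),
                    numeric(1))
  }
  out <- tibble::tibble(q = q, intensity = inten)
  attr(out, "mode") <- mode
  attr(out, "bin_width") <- bin_width
  attr(out, "total_f") <- sum(f)
  class(out) <- c("fab_saxs_profile", class(out))
  out
}

#' Guinier radius of gyration from a SAXS profile
#'
#' Iteratively fits `ln I = ln I(0) - (Rg^2/3) q^2` over the low-q points,
#' shrinking the range until `q_max * Rg <= limit`.
#'
#' @param profile A profile with columns `q` and `intensity`.
#' @param limit Guinier validity limit for `q * Rg` (default 1.3).
#' @param max_iter Iteration cap (default 20).
#' @return A one-row tibble: `rg` (Angstrom), `i0`, `n_points`, `q_max`.
#' @export
guinier_rg <- function(profile, limit = 1.3, max_iter = 20) {
  q <- profile$q
  I <- profile$intensity
  keep <- q > 0 & I > 0
  q <- q[keep]; I <- I[keep]
  if (length(q) < 5) abort("need >= 5 positive low-q points for a Guinier fit")
  idx <- seq_len(min(10L, length(q)))
  for (it in seq_len(max_iter)) {
    if (length(idx) < 5) abort("fewer than 5 points in the converged Guinier range")
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2))
    slope <- stats::coef(fit)[2]
    if (!is.finite(slope) || slope >= 0) abort("Guinier fit has non-negative slope")
    rg <- sqrt(-3 * slope)
    new_idx <- which(q * rg <= limit)
    if (identical(new_idx, idx)) {
      return(tibble::tibble(rg = unname(rg),
                            i0 = exp(unname(stats::coef(fit)[1])),
                            n_points = length(idx), q_max = max(q[idx])))
    }
    idx <- new_idx
  }
  abort(paste0("Guinier range did not converge in ", max_iter, " iterations"))
}

#' Read an experimental SAXS curve
#'
#' Whitespace- or comma-separated 3-column text (`q`, `I`, `sigma`); lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @param q_units `"A^-1"` (default) or `"nm^-1"` (converted to inverse
#'   Angstrom on read).
#' @return A `fab_exp_curve` tibble: `q` (inverse Angstrom), `intensity`,
#'   `sigma` (> 0).
#' @export
read_saxs_curve <- function(path, q_units = c("A^-1", "nm^-1")) {
  q_units <- match.arg(q_units)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) abort(paste0("line ", bad[1], " of ", path, " has fewer than 3 columns"))
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:3])))
  if (any(!is.finite(m))) abort(paste0("non-numeric values in ", path))
  out <- tibble::tibble(q = m[, 1], intensity = m[, 2], sigma = m[, 3])
  if (q_units == "nm^-1") out$q <- out$q / 10
  validate_exp_curve(out)
}

validate_exp_curve <- function(curve) {
  if (any(curve$sigma <= 0)) abort("all sigma values must be > 0")
  if (any(diff(curve$q) <= 0)) abort("q must be strictly increasing")
  class(curve) <- unique(c("fab_exp_curve", class(curve)))
  curve
}

#' Reduced chi-square fit of a calculated profile to an experimental curve
#'
#' The calculated intensity is linearly interpolated onto the experimental q
#' grid (points outside the calculated range are excluded and counted, never
#' extrapolated). The multiplicative scale minimising the weighted misfit has
#' the closed form `c = sum(Ic Ie / s^2) / sum(Ic^2 / s^2)`; the reported
#' statistic is `chi^2 = 1/(N-1) sum(((c Ic - Ie)/s)^2)`. No additive
#' background is fitted by default.
#'
#' @param calc A calculated profile (`q`, `intensity`).
#' @param exp_curve An experimental curve (`q`, `intensity`, `sigma`).
#' @param background Also fit an additive background term?
#' @return A one-row tibble: `chi_square`, `scale`, `background`, `n_points`,
#'   `n_excluded`.
#' @export
chi_square_fit <- function(calc, exp_curve, background = FALSE) {
  qc <- calc$q; Ic_full <- calc$intensity
  qe <- exp_curve$q
  inside <- qe >= min(qc) & qe <= max(qc)
  n_excl <- sum(!inside)
  qe_in <- qe[inside]
  Ie <- exp_curve$intensity[inside]
  s <- exp_curve$sigma[inside]
  if (length(qe_in) < 5) abort("fewer than 5 overlapping q points")
  Ic <- stats::approx(qc, Ic_full, xout = qe_in)$y
  w <- 1 / s^2
  if (!background) {
    sc <- sum(w * Ic * Ie) / sum(w * Ic^2)
    bg <- 0
  } else {
    # weighted least squares for Ie ~ sc*Ic + bg
    A <- cbind(Ic, 1)
    fit <- stats::lm.wfit(A, Ie, w)
    sc <- fit$coefficients[1]; bg <- fit$coefficients[2]
  }
  if (!is.finite(sc) || sc <= 0) abort("non-positive optimal scale; profiles incompatible")
  chi2 <- sum(((sc * Ic + bg - Ie) / s)^2) / (length(Ie) - 1)
  tibble::tibble(chi_square = chi2, scale = unname(sc), background = unname(bg),
                 n_points = length(Ie), n_excluded = n_excl)
}

#' Per-frame SAXS fit of a trajectory against an experimental curve
#'
#' For each frame a Debye profile is computed directly on the experimental q
#' grid and fitted by [chi_square_fit()]; the frame's mass-weighted radius of
#' gyration is reported alongside for chi-square-vs-Rg landscapes. Frames
#' whose computation fails are flagged, not dropped.
#'
#' @param traj A `fab_trajectory` (or list of them, one per repeat).
#' @param exp_curve A `fab_exp_curve`.
#' @param mode,bin_width Forwarded to [debye_profile()]; the default
#'   residue-level coarse-graining keeps per-frame cost manageable.
#' @return A tibble: `frame`, `time_ns`, `chi_square`, `scale`, `rg`,
#'   `repeat_id`, `failed`.
#' @export
fit_trajectory <- function(traj, exp_curve, mode = "residue_cg", bin_width = 0.5) {
  if (inherits(traj, "fab_trajectory")) traj <- list(traj)
  purrr::map_dfr(traj, function(tr) {
    times <- frame_times(tr)
    purrr::map_dfr(seq_along(tr$frames), function(i) {
      res <- tryCatch({
        prof <- debye_profile(tr$topology, q_grid = exp_curve$q, mode = mode,
                              bin_width = bin_width, coords = tr$frames[[i]])
        fit <- chi_square_fit(prof, exp_curve)
        tibble::tibble(frame = i, time_ns = times[i],
                       chi_square = fit$chi_square, scale = fit$scale,
                       rg = radius_of_gyration(tr$topology, tr$frames[[i]]),
                       repeat_id = tr$repeat_id, failed = FALSE)
      }, error = function(e) {
        tibble::tibble(frame = i, time_ns = times[i], chi_square = NA_real_,
                       scale = NA_real_, rg = NA_real_,
                       repeat_id = tr$repeat_id, failed = TRUE)
      })
      res
    })
  })
}

#' Extract the n best-fitting frames across repeats
#'
#' Selects the `n` frames with smallest chi-square over all repeats (ties
#' broken by repeat label, then earlier time), computes their pairwise
#' matched-Calpha RMSD matrix after superposition, and optionally writes the
#' frames as a multi-model PDB.
#'
#' @param fits The fit table from [fit_trajectory()].
#' @param trajectories A `fab_trajectory` or list of them covering every
#'   `repeat_id` in `fits`.
#' @param n Number of frames to extract.
#' @param path Optional output path for a multi-model PDB of the frames.
#' @return A list: `frames` (ranked tibble with rank, repeat_id, frame,
#'   time_ns, chi_square), `rmsd_matrix` (n x n, Angstrom), `path`.
#' @export
top_n_frames <- function(fits, trajectories, n = 10, path = NULL) {
  if (inherits(trajectories, "fab_trajectory")) trajectories <- list(trajectories)
  names(trajectories) <- vapply(trajectories, function(t) t$repeat_id, character(1))
  ok <- dplyr::filter(fits, !.data$failed, is.finite(.data$chi_square))
  if (nrow(ok) < n) abort(paste0("only ", nrow(ok), " usable frames; need ", n))
  ranked <- ok |>
    dplyr::arrange(.data$chi_square, .data$repeat_id, .data$time_ns) |>
    dplyr::slice(seq_len(n)) |>
    dplyr::mutate(rank = dplyr::row_number())
  top <- trajectories[[ranked$repeat_id[1]]]$topology
  ca_idx <- which(top$atom_name == "CA" & !top$is_het)
  coords <- lapply(seq_len(n), function(i) {
    tr <- trajectories[[ranked$repeat_id[i]]]
    if (is.null(tr)) abort(paste0("no trajectory provided for repeat '", ranked$repeat_id[i], "'"))
    tr$frames[[ranked$frame[i]]]
  })
  rmsd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      r <- kabsch_fit(coords[[j]][ca_idx, , drop = FALSE],
                      coords[[i]][ca_idx, , drop = FALSE])$rmsd
      rmsd[i, j] <- rmsd[j, i] <- r
    }
  }
  if (!is.null(path)) write_structure(top, path, frames = coords)
  list(frames = ranked[, c("rank", "repeat_id", "frame", "time_ns", "chi_square", "rg")],
       rmsd_matrix = rmsd, path = path)
}
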