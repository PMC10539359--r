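#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two point sets in correspondence, via the SVD of the
#' weighted covariance matrix. Reflections are never returned: when the
#' covariance determinant is negative, the smallest singular direction is
#' flipped.
#'
#' @param mobile,reference N x 3 coordinate matrices in correspondence, N >= 3.
#' @param weights Optional non-negative weights of length N (default uniform).
#' @return A `fab_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, weighted), `rotation_angle`
#'   (degrees, in \[0, 180\]) and `rotation_axis` (unit vector). Applying
#'   `rotation %*% x + translation` to each mobile point superposes it onto
#'   the reference.
#' @examples
#' set.seed(1)
#' ref <- matrix(rnorm(30), 10, 3)
#' R <- rotation_about_axis(c(0, 0, 1), 30)
#' mob <- ref %*% t(R) + 5
#' kabsch_fit(mob, ref)$rmsd
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n || ncol(mobile) != 3 || ncol(reference) != 3) {
    abort("mobile and reference must be matching N x 3 matrices with N >= 3")
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    abort("weights must be N non-negative values with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (min(sv$d[1:2]) < 1e-12 * max(sv$d, 1e-300)) {
    abort("degenerate (collinear or coincident) point configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  resid <- P %*% t(R) - Q
  rmsd <- sqrt(sum(w * rowSums(resid^2)))
  aa <- rotation_axis_angle(R)
  structure(
    list(rotation = R, translation = t_vec, rmsd = rmsd,
         rotation_angle = aa$angle, rotation_axis = aa$axis),
    class = "fab_transform"
  )
}

# axis + angle (degrees) of a proper rotation matrix
rotation_axis_angle <- function(R) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-9) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (abs(pi - ang) > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  } else {
    # near 180 deg: axis from the symmetric part, largest-column pick
    B <- (R + diag(3)) / 2
    j <- which.max(diag(B))
    ax <- B[, j] / sqrt(B[j, j])
  }
  list(axis = unit_vec(ax), angle = rad2deg(ang))
}

#' @export
print.fab_transform <- function(x, ...) {
  cat(sprintf("<fab_transform> rotation %.2f deg, rmsd %.4f A\n",
              x$rotation_angle, x$rmsd))
  invisible(x)
}

#' @rdname kabsch_fit
#' @param x A `fab_transform`.
#' @param ... Unused.
#' @method glance fab_transform
#' @export
glance.fab_transform <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd, rotation_angle = x$rotation_angle,
    axis_x = x$rotation_axis[1], axis_y = x$rotation_axis[2],
    axis_z = x$rotation_axis[3],
    tx = x$translation[1], ty = x$translation[2], tz = x$translation[3]
  )
}

# matched Calpha tables of two annotated structures over selected domains;
# correspondence is identity of (domain, residue_number, insertion_code)
matched_ca_pairs <- function(a, b, domains) {
  take <- function(fab) {
    purrr::map_dfr(domains, function(d) {
      dplyr::mutate(domain_ca(fab, d), domain = d)
    })
  }
  ta <- take(a); tb <- take(b)
  key <- function(t) paste(t$domain, t$residue_number, t$insertion_code)
  ka <- key(ta); kb <- key(tb)
  common <- intersect(ka, kb)
  list(
    a = ta[match(common, ka), , drop = FALSE],
    b = tb[match(common, kb), , drop = FALSE]
  )
}

selection_domains <- function(selection) {
  switch(selection,
    all = c("VH", "VL", "CH1", "CL"),
    variable = c("VH", "VL"),
    constant = c("CH1", "CL"),
    abort(paste0("unknown selection: ", selection))
  )
}

#' Matched-residue Calpha RMSD between two Fab structures
#'
#' Residues are matched by identical (chain role, residue number, insertion
#' code) across the two annotated structures; superposition and RMSD are
#' restricted to the Calpha atoms of the chosen selection.
#'
#' @param a,b `fab_structure` objects.
#' @param selection `"all"`, `"variable"`, `"constant"`, or a character vector
#'   of domain names (subset of VH, VL, CH1, CL).
#' @return A one-row tibble: `selection`, `rmsd` (Angstrom), `n_matched`.
#' @examples
#' f1 <- build_synthetic_crystal_form("triclinic")
#' f2 <- build_synthetic_crystal_form("hexagonal")
#' rmsd_matched_ca(f1, f2, "variable")
#' @export
rmsd_matched_ca <- function(a, b, selection = "all") {
  domains <- if (length(selection) == 1 && selection %in% c("all", "variable", "constant")) {
    selection_domains(selection)
  } else {
    bad <- setdiff(selection, c("VH", "VL", "CH1", "CL"))
    if (length(bad) > 0) abort(paste0("unknown domain(s): ", paste(bad, collapse = ", ")))
    selection
  }
  pairs <- matched_ca_pairs(a, b, domains)
  n <- nrow(pairs$a)
  if (n < 3) abort(paste0("only ", n, " matched residues; need >= 3"))
  fit <- kabsch_fit(coords_matrix(pairs$a), coords_matrix(pairs$b))
  tibble::tibble(
    selection = paste(selection, collapse = "+"),
    rmsd = fit$rmsd, n_matched = n
  )
}

#' Windowed per-domain RMSF over a trajectory
#'
#' For the frames falling in a time window, the domain's Calpha coordinates
#' are superposed onto the window-mean structure (one mean-fit-recompute
#' iteration, seeded by the raw coordinate mean) and the per-residue
#' root-mean-square fluctuation about the refined mean is returned.
#'
#' @param traj A `fab_trajectory` (see [read_trajectory()]).
#' @param fab The annotated `fab_structure` matching the trajectory topology.
#' @param domain One of `"VH"`, `"VL"`, `"CH1"`, `"CL"`.
#' @param window `c(start_ns, end_ns)`; frames with `start <= t < end` are
#'   used (the final frame of the trajectory is included when `end` equals the
#'   trajectory end time).
#' @return A tibble with `chain_id`, `residue_number`, `insertion_code`,
#'   `rmsf` (Angstrom), plus `domain` and window columns.
#' @export
rmsf_windowed <- function(traj, fab, domain, window) {
  stopifnot(inherits(traj, "fab_trajectory"))
  times <- frame_times(traj)
  keep <- which(times >= window[1] & (times < window[2] |
                (times == window[2] & window[2] == max(times))))
  if (length(keep) < 2) abort("window must contain at least 2 frames")
  ca <- domain_ca(fab, domain)
  idx <- match_atom_rows(fab$atoms, ca)
  sub <- lapply(traj$frames[keep], function(m) m[idx, , drop = FALSE])
  mean0 <- Reduce(`+`, sub) / length(sub)
  fit_to <- function(frames, ref) {
    lapply(frames, function(m) {
      f <- kabsch_fit(m, ref)
      sweep(m %*% t(f$rotation), 2, -f$translation, FUN = "-")
    })
  }
  fitted <- fit_to(sub, mean0)
  mean1 <- Reduce(`+`, fitted) / length(fitted)
  fitted <- fit_to(sub, mean1)
  mean2 <- Reduce(`+`, fitted) / length(fitted)
  dev2 <- Reduce(`+`, lapply(fitted, function(m) rowSums((m - mean2)^2))) / length(fitted)
  tibble::tibble(
    chain_id = ca$chain_id, residue_number = ca$residue_number,
    insertion_code = ca$insertion_code, rmsf = sqrt(dev2),
    domain = domain, window_start_ns = window[1], window_end_ns = window[2]
  )
}

# row indices in the topology atom table of the atoms in `subset`
match_atom_rows <- function(atoms, subset) {
  key <- function(t) paste(t$chain_id, t$residue_number, t$insertion_code, t$atom_name)
  idx <- match(key(subset), key(atoms))
  if (anyNA(idx)) abort("subset atoms not found in topology")
  idx
}
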