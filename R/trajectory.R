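#' Construct a trajectory object
#'
#' @param topology An atom table ([read_structure()]/[as_atomset()]).
#' @param frames List of N x 3 coordinate matrices (Angstrom), N = atom count.
#' @param dt_ns Time between frames in ns (> 0).
#' @param t0_ns Time of the first frame in ns.
#' @param repeat_id Label of the simulation repeat this trajectory belongs to.
#' @return A `fab_trajectory`: list with the fields above.
#' @export
fab_trajectory <- function(topology, frames, dt_ns, t0_ns = 0, repeat_id = "r1") {
  topology <- validate_atoms(tibble::as_tibble(topology))
  class(topology) <- c("fab_atoms", class(topology))
  if (!is.list(frames) || length(frames) == 0) abort("frames must be a non-empty list")
  n <- nrow(topology)
  ok <- vapply(frames, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3,
               logical(1))
  if (!all(ok)) {
    abort(paste0("frame ", which(!ok)[1], " does not match the topology atom count (", n, ")"))
  }
  stop_if_not_scalar(dt_ns, "dt_ns")
  if (dt_ns <= 0) abort("dt_ns must be > 0")
  structure(
    list(topology = topology, frames = frames, dt_ns = dt_ns, t0_ns = t0_ns,
         repeat_id = repeat_id),
    class = "fab_trajectory"
  )
}

#' @export
print.fab_trajectory <- function(x, ...) {
  cat(sprintf("<fab_trajectory> %d frames x %d atoms, dt %.4g ns, repeat '%s'\n",
              length(x$frames), nrow(x$topology), x$dt_ns, x$repeat_id))
  invisible(x)
}

frame_times <- function(traj) {
  traj$t0_ns + (seq_along(traj$frames) - 1) * traj$dt_ns
}

check_topology_match <- function(traj, atoms) {
  if (nrow(traj$topology) != nrow(atoms)) {
    abort(paste0("topology mismatch: trajectory has ", nrow(traj$topology),
                 " atoms, structure has ", nrow(atoms)))
  }
  invisible(TRUE)
}

#' Read a trajectory from multi-model PDB or DCD files
#'
#' Multiple trajectory files are concatenated in argument order. DCD files
#' require a separate topology; a multi-model PDB is its own topology.
#' XTC is not supported; convert to DCD or multi-model PDB first.
#'
#' @param topology Path to a PDB/mmCIF topology (ignored for a single
#'   multi-model PDB given as `paths`, where the first model is the topology).
#' @param paths Character vector of trajectory file paths (`.pdb` or `.dcd`).
#' @param dt_ns Time between frames in ns.
#' @param t0_ns Time of the first frame in ns.
#' @param repeat_id Repeat label.
#' @return A `fab_trajectory`.
#' @export
read_trajectory <- function(topology, paths, dt_ns, t0_ns = 0, repeat_id = "r1") {
  top <- read_structure(topology)
  frames <- list()
  for (p in paths) {
    ext <- tolower(tools::file_ext(p))
    if (ext == "xtc") {
      abort("XTC reading is not supported; convert to DCD or multi-model PDB")
    } else if (ext == "dcd") {
      xyz <- bio3d::read.dcd(p, verbose = FALSE)
      fr <- lapply(seq_len(nrow(xyz)), function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    } else {
      mm <- read_structure(p, multi = TRUE)
      if (nrow(mm$topology) != nrow(top)) {
        abort(paste0("atom count mismatch: topology has ", nrow(top),
                     " atoms, ", p, " has ", nrow(mm$topology)))
      }
      fr <- mm$frames
    }
    bad <- which(vapply(fr, nrow, integer(1)) != nrow(top))
    if (length(bad) > 0) {
      abort(paste0("atom count mismatch in ", p, " frame ", bad[1], ": expected ",
                   nrow(top), ", got ", nrow(fr[[bad[1]]])))
    }
    frames <- c(frames, fr)
  }
  fab_trajectory(top, frames, dt_ns = dt_ns, t0_ns = t0_ns, repeat_id = repeat_id)
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt(sum_i m_i |r_i - r_cm|^2 / sum_i m_i)`.
#'
#' @param atoms Atom table providing masses.
#' @param coords Optional N x 3 coordinate matrix overriding the table's
#'   coordinates (e.g. a trajectory frame).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(atoms, coords = NULL) {
  if (inherits(atoms, "fab_structure")) atoms <- atoms$atoms
  xyz <- if (is.null(coords)) coords_matrix(atoms) else as.matrix(coords)
  m <- atoms$mass
  if (length(m) != nrow(xyz)) abort("coords do not match the atom table")
  tot <- sum(m)
  if (tot <= 0) abort("total mass must be positive")
  cm <- colSums(xyz * m) / tot
  sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / tot)
}

#' Radius-of-gyration time series
#'
#' @param traj A `fab_trajectory`.
#' @return A tibble: `frame`, `time_ns`, `rg` (Angstrom), `rg_nm`, `repeat_id`.
#' @export
rg_timeseries <- function(traj) {
  stopifnot(inherits(traj, "fab_trajectory"))
  rg <- vapply(traj$frames, function(m) radius_of_gyration(traj$topology, m),
               numeric(1))
  tibble::tibble(
    frame = seq_along(traj$frames), time_ns = frame_times(traj),
    rg = rg, rg_nm = rg / 10, repeat_id = traj$repeat_id
  )
}

#' Calpha RMSD to the starting frame
#'
#' Each frame's selected Calpha set is superposed onto frame 1 by
#' [kabsch_fit()]; the post-fit RMSD is reported, so global rigid motion does
#' not contribute.
#'
#' @param traj A `fab_trajectory`.
#' @param selection Optional logical/integer vector selecting topology rows;
#'   default: all Calpha atoms.
#' @return A tibble: `frame`, `time_ns`, `rmsd` (Angstrom), `repeat_id`.
#' @export
rmsd_to_start <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "fab_trajectory"))
  idx <- if (is.null(selection)) {
    which(traj$topology$atom_name == "CA" & !traj$topology$is_het)
  } else if (is.logical(selection)) which(selection) else as.integer(selection)
  if (length(idx) == 0) abort("empty atom selection")
  ref <- traj$frames[[1]][idx, , drop = FALSE]
  rmsd <- vapply(traj$frames, function(m) {
    kabsch_fit(m[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  tibble::tibble(
    frame = seq_along(traj$frames), time_ns = frame_times(traj),
    rmsd = rmsd, repeat_id = traj$repeat_id
  )
}

#' Aggregate repeat time series into mean and SEM
#'
#' All repeats must share an identical time grid (no interpolation is
#' performed; mismatched grids are an error). SEM is the sample standard
#' deviation across repeats divided by `sqrt(n)`.
#'
#' @param series List of tibbles with columns `time_ns` and a value column.
#' @param value Name of the value column (default: the first column that is
#'   not `frame`/`time_ns`/`repeat_id`).
#' @return A `fab_timeseries_stat` tibble: `time_ns`, `mean`, `sem`,
#'   `n_repeats`, `metric`.
#' @export
aggregate_repeats <- function(series, value = NULL) {
  if (!is.list(series) || length(series) < 2) abort("need >= 2 repeat series")
  if (is.null(value)) {
    cand <- setdiff(names(series[[1]]),
                    c("frame", "time_ns", "repeat_id", "failed", "n_warnings"))
    value <- cand[1]
  }
  grid <- series[[1]]$time_ns
  for (i in seq_along(series)) {
    if (length(series[[i]]$time_ns) != length(grid) ||
        any(abs(series[[i]]$time_ns - grid) > 1e-9)) {
      abort(paste0("repeat ", i, " is not on the common time grid (no interpolation is done)"))
    }
  }
  vals <- vapply(series, function(s) as.numeric(s[[value]]), numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  out <- tibble::tibble(
    time_ns = grid,
    mean = rowMeans(vals),
    sem = apply(vals, 1, stats::sd) / sqrt(ncol(vals)),
    n_repeats = ncol(vals),
    metric = value
  )
  class(out) <- c("fab_timeseries_stat", class(out))
  out
}

#' Detect inter-chain hydrogen bonds between heavy and light chains
#'
#' Donor/acceptor candidates are nitrogen and oxygen atoms. A pair is counted
#' when the donor-acceptor heavy-atom distance is at most `d_max` and, when
#' hydrogens are present on the donor residue, the best D-H...A angle is at
#' least `angle_min`. Only pairs crossing the heavy/light chain boundary are
#' reported, deduplicated to residue pairs.
#'
#' @param fab A `fab_structure`.
#' @param d_max Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_min D-H...A angle cutoff in degrees (default 120), applied
#'   only when hydrogens are present.
#' @return A tibble of residue pairs: donor/acceptor chain, residue number and
#'   name, distance, and the angle used (NA without hydrogens).
#' @export
interchain_hbonds <- function(fab, d_max = 3.5, angle_min = 120) {
  atoms <- protein_atoms(fab$atoms)
  pol <- dplyr::filter(atoms, .data$element %in% c("N", "O"),
                       .data$chain_id %in% c(fab$heavy_chain, fab$light_chain))
  hyd <- dplyr::filter(atoms, .data$element == "H")
  has_h <- nrow(hyd) > 0
  xyz <- coords_matrix(pol)
  out <- list()
  for (i in seq_len(nrow(pol))) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    cand <- which(d <= d_max & d > 0.1 & pol$chain_id != pol$chain_id[i])
    for (j in cand) {
      # treat i as donor, j as acceptor; require a donor-side H when present
      ang <- NA_real_
      if (has_h) {
        hh <- dplyr::filter(hyd, .data$chain_id == pol$chain_id[i],
                            .data$residue_number == pol$residue_number[i])
        if (nrow(hh) == 0) next
        hxyz <- coords_matrix(hh)
        dh <- sqrt(rowSums(sweep(hxyz, 2, xyz[i, ])^2))
        hh <- hh[dh <= 1.3, , drop = FALSE]
        hxyz <- hxyz[dh <= 1.3, , drop = FALSE]
        if (nrow(hh) == 0) next
        angs <- vapply(seq_len(nrow(hh)), function(k) {
          vec_angle(xyz[i, ] - hxyz[k, ], xyz[j, ] - hxyz[k, ])
        }, numeric(1))
        ang <- max(angs)
        if (ang < angle_min) next
      }
      out[[length(out) + 1]] <- tibble::tibble(
        donor_chain = pol$chain_id[i], donor_residue = pol$residue_number[i],
        donor_resname = pol$residue_name[i],
        acceptor_chain = pol$chain_id[j], acceptor_residue = pol$residue_number[j],
        acceptor_resname = pol$residue_name[j],
        distance = d[j], angle = ang
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      donor_chain = character(), donor_residue = integer(),
      donor_resname = character(), acceptor_chain = character(),
      acceptor_residue = integer(), acceptor_resname = character(),
      distance = numeric(), angle = numeric()
    ))
  }
  res <- dplyr::bind_rows(out)
  # deduplicate to residue pairs regardless of donor/acceptor direction
  a <- paste(res$donor_chain, res$donor_residue)
  b <- paste(res$acceptor_chain, res$acceptor_residue)
  key <- ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  res[!duplicated(key), , drop = FALSE]
}
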