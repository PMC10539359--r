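#' Van der Waals radii and quadrature settings for SASA
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Number of quadrature points per atom sphere
#'   (default 960, deterministic golden-spiral set; must be >= 60).
#' @param radii Named vector of per-element van der Waals radii in Angstrom.
#' @param fallback_radius Optional radius used for elements missing from
#'   `radii`; unknown elements are an error when `NULL`.
#' @return A `fab_radii` list.
#' @export
radii_set <- function(probe_radius = 1.4, n_sphere_points = 960,
                      radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20),
                      fallback_radius = NULL) {
  if (any(radii <= 0)) abort("all radii must be > 0")
  if (n_sphere_points < 60) abort("n_sphere_points must be >= 60")
  if (probe_radius < 0) abort("probe_radius must be >= 0")
  structure(
    list(radii = radii, probe_radius = probe_radius,
         n_sphere_points = as.integer(n_sphere_points),
         fallback_radius = fallback_radius),
    class = "fab_radii"
  )
}

# deterministic quasi-uniform unit-sphere point set (golden spiral / Fibonacci)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# deterministic quasi-random rotation for atom index i (Shoemake quaternion
# from low-discrepancy sequences); decorrelates the quadrature error across
# atoms so totals are nearly invariant under global rotation of the structure
scramble_rotation <- function(i) {
  u1 <- (i * (sqrt(2) - 1)) %% 1
  u2 <- (i * (sqrt(3) - 1)) %% 1
  u3 <- (i * (sqrt(5) - 2)) %% 1
  q <- c(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
         sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

atom_radii <- function(atoms, radii) {
  r <- unname(radii$radii[atoms$element])
  miss <- is.na(r)
  if (any(miss)) {
    if (is.null(radii$fallback_radius)) {
      abort(paste0("no van der Waals radius for element(s): ",
                   paste(unique(atoms$element[miss]), collapse = ", ")))
    }
    r[miss] <- radii$fallback_radius
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe over the structure: each atom's extended sphere of
#' radius `r_i + probe` is sampled with a deterministic quasi-uniform point
#' set (a golden-spiral layout, given a fixed quasi-random orientation per
#' atom), and the per-atom SASA is `4 pi (r_i + probe)^2` times the fraction
#' of points not buried inside any neighbour's extended sphere. Points within
#' one point-spacing of a burial boundary contribute fractionally (a linear
#' transition), which damps the aliasing error of a hard in/out count.
#' Waters and heteroatoms are excluded unless `include_hetero = TRUE`;
#' hydrogens take part only if present in the input.
#'
#' @param atoms Atom table or `fab_structure`.
#' @param radii A [radii_set()].
#' @param coords Optional N x 3 matrix overriding the table's coordinates
#'   (N = rows of the *full* atom table; e.g. a trajectory frame).
#' @param include_hetero Include HETATM/water records?
#' @return The atom table (filtered as computed) with an added `sasa` column
#'   in Angstrom squared.
#' @examples
#' carbon <- as_atomset(data.frame(element = "C", atom_name = "C",
#'   residue_name = "UNK", residue_number = 1, chain_id = "A",
#'   x = 0, y = 0, z = 0))
#' sum(shrake_rupley(carbon)$sasa) # ~ 4*pi*(1.7+1.4)^2
#' @export
shrake_rupley <- function(atoms, radii = radii_set(), coords = NULL,
                          include_hetero = FALSE) {
  if (inherits(atoms, "fab_structure")) atoms <- atoms$atoms
  if (!is.null(coords)) atoms <- set_coords(atoms, as.matrix(coords))
  atoms <- protein_atoms(atoms, include_hetero = include_hetero)
  if (nrow(atoms) == 0) abort("no atoms left after filtering")
  r <- atom_radii(atoms, radii)
  rp <- radii$probe_radius
  xyz <- coords_matrix(atoms)
  n <- nrow(xyz)
  sp <- golden_spiral_points(radii$n_sphere_points)
  ext <- r + rp
  sasa <- numeric(n)
  np <- radii$n_sphere_points
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ext[i] + ext)^2 & d2 > 1e-12)
    pts <- sweep((sp %*% scramble_rotation(i)) * ext[i], 2, xyz[i, ], FUN = "+")
    if (length(nb) == 0) {
      frac <- 1
    } else {
      # signed margin of each test point to the nearest blocking sphere; the
      # buried/exposed boundary is smoothed linearly over one point spacing,
      # which suppresses the aliasing error of a hard in/out count
      h <- 2 * ext[i] * sqrt(pi / np)
      marg <- rep(Inf, np)
      nb <- nb[order(d2[nb])]
      for (j in nb) {
        act <- marg > -h
        if (!any(act)) break
        dd <- sqrt(rowSums(sweep(pts[act, , drop = FALSE], 2, xyz[j, ])^2)) - ext[j]
        marg[act] <- pmin(marg[act], dd)
      }
      frac <- mean(pmin(1, pmax(0, 0.5 + marg / h)))
    }
    sasa[i] <- 4 * pi * ext[i]^2 * frac
  }
  atoms$sasa <- sasa
  atoms
}

#' Default aggregation-prone-region (APR) windows
#'
#' The four APR residue windows with elevated solvent exposure under low-pH
#' stress: heavy-chain V173-V188 (CH1) and light-chain T129-F139 (CL),
#' L47-A51 (VL) and T31-Y36 (VL). Further windows can be appended by the
#' caller; the same table ships as `extdata/apr_windows.tsv`.
#'
#' @return A tibble: `label`, `chain_role` (`"heavy"`/`"light"`),
#'   `first_residue`, `last_residue`.
#' @export
default_apr_windows <- function() {
  tibble::tribble(
    ~label,            ~chain_role, ~first_residue, ~last_residue,
    "heavy_V173-V188", "heavy",     173L,           188L,
    "light_T129-F139", "light",     129L,           139L,
    "light_L47-A51",   "light",      47L,            51L,
    "light_T31-Y36",   "light",      31L,            36L
  )
}

#' Read an APR window table from TSV
#'
#' @param path TSV with columns label, chain_role, first_residue,
#'   last_residue.
#' @return The window tibble.
#' @export
read_apr_windows <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("label", "chain_role", "first_residue", "last_residue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("APR table missing columns: ", paste(miss, collapse = ", ")))
  if (any(df$first_residue > df$last_residue)) abort("APR window with first > last")
  df
}

#' Per-window SASA over APR residue windows
#'
#' Each window's value is the sum of per-atom SASA over all atoms of the
#' window's residues, computed in the context of the whole structure.
#' Residues referenced by a window but absent from the structure are reported
#' in the `missing_residues` list-column, never silently ignored.
#'
#' @param fab A `fab_structure`.
#' @param windows A window table as from [default_apr_windows()].
#' @param radii A [radii_set()].
#' @param coords Optional coordinate override (full atom table rows).
#' @param per_atom Optional precomputed result of [shrake_rupley()] to reuse.
#' @return A tibble: `label`, `chain_id`, `sasa` (A^2), `sasa_nm2`,
#'   `n_atoms`, `missing_residues` (list of integer vectors).
#' @export
apr_sasa <- function(fab, windows = default_apr_windows(), radii = radii_set(),
                     coords = NULL, per_atom = NULL) {
  if (is.null(per_atom)) {
    per_atom <- shrake_rupley(fab$atoms, radii = radii, coords = coords)
  }
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    ch <- if (w$chain_role == "heavy") fab$heavy_chain else fab$light_chain
    rows <- dplyr::filter(per_atom, .data$chain_id == ch,
                          .data$residue_number >= w$first_residue,
                          .data$residue_number <= w$last_residue)
    present <- unique(rows$residue_number)
    wanted <- seq.int(w$first_residue, w$last_residue)
    tibble::tibble(
      label = w$label, chain_id = ch,
      sasa = sum(rows$sasa), sasa_nm2 = sum(rows$sasa) / 100,
      n_atoms = nrow(rows),
      missing_residues = list(setdiff(wanted, present))
    )
  })
}

#' APR SASA time series over a trajectory
#'
#' @param traj A `fab_trajectory`.
#' @param fab The annotated topology.
#' @param windows,radii As in [apr_sasa()].
#' @return A tibble with one row per (frame, window): `frame`, `time_ns`,
#'   `label`, `sasa`, `repeat_id`.
#' @export
apr_sasa_timeseries <- function(traj, fab, windows = default_apr_windows(),
                                radii = radii_set()) {
  stopifnot(inherits(traj, "fab_trajectory"))
  check_topology_match(traj, fab$atoms)
  times <- frame_times(traj)
  purrr::map_dfr(seq_along(traj$frames), function(i) {
    res <- apr_sasa(fab, windows = windows, radii = radii,
                    coords = traj$frames[[i]])
    tibble::tibble(frame = i, time_ns = times[i], label = res$label,
                   sasa = res$sasa, repeat_id = traj$repeat_id)
  })
}

#' Time-window average with SEM over repeats
#'
#' For each repeat the time-mean of the value over `window` is taken; the
#' cross-repeat mean and SEM (sample SD / sqrt(n)) are returned.
#'
#' @param series List of per-repeat tibbles with a `time_ns` column.
#' @param window `c(start_ns, end_ns)`; frames with `start <= t <= end` are
#'   averaged.
#' @param value Value column name (default: first non-bookkeeping column).
#' @return A one-row tibble: `mean`, `sem`, `n_repeats`, window bounds.
#' @export
window_average <- function(series, window, value = NULL) {
  if (!is.list(series) || length(series) < 2) abort("need >= 2 repeats")
  if (is.null(value)) {
    cand <- setdiff(names(series[[1]]),
                    c("frame", "time_ns", "repeat_id", "label", "failed", "n_warnings"))
    value <- cand[1]
  }
  means <- vapply(seq_along(series), function(i) {
    s <- series[[i]]
    keep <- s$time_ns >= window[1] & s$time_ns <= window[2]
    if (!any(keep)) abort(paste0("window [", window[1], ", ", window[2],
                                 "] ns is empty in repeat ", i))
    mean(as.numeric(s[[value]][keep]))
  }, numeric(1))
  tibble::tibble(
    mean = mean(means), sem = sem(means), n_repeats = length(means),
    window_start_ns = window[1], window_end_ns = window[2], metric = value
  )
}
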