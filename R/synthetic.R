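#' Specification for a synthetic Fab-like structure
#'
#' @param atoms_per_domain Calpha count per domain (>= 20; default 60).
#' @param domain_radius Radius of each compact domain cluster in Angstrom
#'   (default 12).
#' @param designed_elbow Target elbow angle in degrees, in (0, 180]
#'   (default 150).
#' @param inter_domain_separation Gap between paired domains in Angstrom
#'   (default 6).
#' @param seed Integer seed; every generator output is a pure function of its
#'   spec including the seed.
#' @return A `toy_fab_spec` list.
#' @export
toy_fab_spec <- function(atoms_per_domain = 60, domain_radius = 12,
                         designed_elbow = 150, inter_domain_separation = 6,
                         seed = 1) {
  if (atoms_per_domain < 20) abort("atoms_per_domain must be >= 20")
  if (designed_elbow <= 0 || designed_elbow > 180) {
    abort("designed_elbow must be in (0, 180] degrees")
  }
  if (domain_radius <= 0 || inter_domain_separation < 0) {
    abort("domain_radius must be > 0 and inter_domain_separation >= 0")
  }
  structure(
    list(atoms_per_domain = as.integer(atoms_per_domain),
         domain_radius = domain_radius, designed_elbow = designed_elbow,
         inter_domain_separation = inter_domain_separation,
         seed = as.integer(seed)),
    class = "toy_fab_spec"
  )
}

# compact random cluster: Gaussian-placed points kept inside a sphere with a
# minimum inter-point spacing, rejection-sampled deterministically from rng
random_domain_cluster <- function(n, radius, min_spacing = 2.5, rng) {
  pts <- matrix(NA_real_, n, 3)
  k <- 0
  tries <- 0
  while (k < n) {
    tries <- tries + 1
    if (tries > 50000) abort("could not place domain atoms; lower atoms_per_domain or raise domain_radius")
    p <- rng(3) * radius / 2
    if (vnorm(p) > radius) next
    if (k > 0) {
      d2 <- rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_spacing^2) next
    }
    k <- k + 1
    pts[k, ] <- p
  }
  pts
}

# deterministic synthetic residue sequence cycling through the 20 amino acids
synthetic_sequence <- function(n, offset = 0) {
  aa <- residue_formula_table()$residue_name
  aa[((seq_len(n) - 1 + offset) %% length(aa)) + 1]
}

#' Build a synthetic Fab-like structure with a designed elbow angle
#'
#' Constructs four compact random domains with exact pseudo-twofold symmetry:
#' the light-chain variable domain (VL) is generated as a random cluster and
#' VH is its exact 180-degree copy about the variable-region dyad axis;
#' CL/CH1 are built the same way about the constant-region dyad. The two dyad
#' axes are placed symmetrically about the inter-module vector so that, under
#' the orientation convention of [elbow_angle()], they subtend exactly the
#' designed elbow angle. All atoms are Calpha carbons with a deterministic
#' synthetic residue sequence, so geometry, SASA, Rg, SAXS and charge
#' operations all work on the result.
#'
#' @param spec A [toy_fab_spec()].
#' @return An annotated `fab_structure` with attributes `designed_elbow`,
#'   `dyad_variable`, `dyad_constant`, `hinge_point` and `module_axis_n`
#'   (ground-truth geometry used by [make_hinge_trajectory()]).
#' @examples
#' fab <- build_toy_fab(toy_fab_spec(designed_elbow = 150, seed = 7))
#' elbow_angle(fab)$elbow_angle
#' @export
build_toy_fab <- function(spec) {
  stopifnot(inherits(spec, "toy_fab_spec"))
  set.seed(spec$seed)
  rng <- function(k) stats::rnorm(k)
  n <- spec$atoms_per_domain
  half <- spec$designed_elbow / 2
  # dyad axes in the xz-plane, symmetric about +z (the constant->variable axis)
  a_v <- c(sin(deg2rad(half)), 0, cos(deg2rad(half)))
  a_c <- c(-sin(deg2rad(half)), 0, cos(deg2rad(half)))
  # limb directions bend away from the hinge so that the module separation is
  # 2 L sin(elbow/2): a straight (180 deg) Fab is maximally extended and
  # opening the hinge in a trajectory increases the radius of gyration
  hinge <- c(0, 0, 0)
  L_arm <- 2 * spec$domain_radius + spec$inter_domain_separation
  th <- deg2rad((180 - spec$designed_elbow) / 2)
  d_v <- c(-sin(th), 0, cos(th))
  d_c <- c(-sin(th), 0, -cos(th))
  p_v <- hinge + L_arm * d_v  # variable-module centre (on the variable dyad axis)
  p_c <- hinge + L_arm * d_c  # constant-module centre
  offset <- spec$domain_radius + spec$inter_domain_separation / 2 + 1.5
  m_v <- unit_vec(pracma_cross(a_v, c(0, 1, 0)))
  m_c <- unit_vec(pracma_cross(a_c, c(0, 1, 0)))
  vl <- sweep(random_domain_cluster(n, spec$domain_radius, rng = rng), 2,
              p_v + offset * m_v, FUN = "+")
  cl <- sweep(random_domain_cluster(n, spec$domain_radius, rng = rng), 2,
              p_c + offset * m_c, FUN = "+")
  rot_about <- function(xyz, point, axis) {
    R <- rotation_about_axis(axis, 180)
    sweep(sweep(xyz, 2, point) %*% t(R), 2, point, FUN = "+")
  }
  vh <- rot_about(vl, p_v, a_v)
  ch1 <- rot_about(cl, p_c, a_c)
  mk <- function(xyz, chain, res_start, seq_offset) {
    nn <- nrow(xyz)
    tibble::tibble(
      element = "C", atom_name = "CA",
      residue_name = synthetic_sequence(nn, seq_offset),
      residue_number = seq.int(res_start, length.out = nn),
      chain_id = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  atoms <- dplyr::bind_rows(
    mk(vh, "H", 1, 0), mk(ch1, "H", n + 1, n),
    mk(vl, "L", 1, 5), mk(cl, "L", n + 1, 5 + n)
  )
  atoms$atom_id <- seq_len(nrow(atoms))
  fab <- annotate_fab(as_atomset(atoms), heavy = "H", light = "L",
                      boundaries = list(VH = c(1L, n), VL = c(1L, n),
                                        CH1 = c(n + 1L, 2L * n),
                                        CL = c(n + 1L, 2L * n)))
  attr(fab, "designed_elbow") <- spec$designed_elbow
  attr(fab, "dyad_variable") <- a_v
  attr(fab, "dyad_constant") <- a_c
  attr(fab, "hinge_point") <- hinge
  n_axis <- pracma_cross(a_c, a_v)
  if (vnorm(n_axis) < 1e-8) {
    # antiparallel dyads (designed elbow 180): the construction lies in the
    # xz-plane, so the in-plane hinge normal is +y
    n_axis <- c(0, 1, 0)
  }
  attr(fab, "module_axis_n") <- unit_vec(n_axis)
  attr(fab, "spec") <- spec
  fab
}

# cross product (kept local; avoids pulling a dependency for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Hinge-motion schedule for synthetic trajectories
#'
#' @param angles Per-frame target elbow angles in degrees (each in (0, 180]).
#' @param noise_sigma Isotropic Gaussian noise added per coordinate, Angstrom.
#' @param dt_ns Time between frames (ns).
#' @param n_repeats Number of independent repeats (seed offsets).
#' @param seed Base seed.
#' @return A `hinge_schedule` list.
#' @export
hinge_schedule <- function(angles, noise_sigma = 0, dt_ns = 0.1,
                           n_repeats = 1, seed = 1) {
  if (any(angles <= 0 | angles > 180)) abort("schedule angles must be in (0, 180]")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(
    list(angles = as.numeric(angles), noise_sigma = noise_sigma,
         dt_ns = dt_ns, n_repeats = as.integer(n_repeats),
         seed = as.integer(seed)),
    class = "hinge_schedule"
  )
}

#' Generate hinge-motion trajectories from a synthetic Fab
#'
#' For each frame the variable module (VH + VL) is rotated about the hinge
#' normal through the hinge point so that the designed elbow angle meets the
#' scheduled target, then independent Gaussian noise of the schedule's sigma
#' is added to every coordinate. Repeats differ only by a deterministic seed
#' offset; the schedule (and time grid) is shared.
#'
#' @param fab A structure from [build_toy_fab()] (its ground-truth geometry
#'   attributes are required).
#' @param schedule A [hinge_schedule()].
#' @return A list of `fab_trajectory`, one per repeat.
#' @export
make_hinge_trajectory <- function(fab, schedule) {
  stopifnot(inherits(schedule, "hinge_schedule"))
  base_elbow <- attr(fab, "designed_elbow")
  hinge <- attr(fab, "hinge_point")
  n_axis <- attr(fab, "module_axis_n")
  if (is.null(base_elbow) || is.null(hinge) || is.null(n_axis)) {
    abort("fab lacks generator ground-truth attributes; build it with build_toy_fab()")
  }
  atoms <- fab$atoms
  var_rows <- which(
    (atoms$chain_id == fab$heavy_chain &
       atoms$residue_number >= fab$domain_ranges$VH[1] &
       atoms$residue_number <= fab$domain_ranges$VH[2]) |
    (atoms$chain_id == fab$light_chain &
       atoms$residue_number >= fab$domain_ranges$VL[1] &
       atoms$residue_number <= fab$domain_ranges$VL[2]))
  xyz0 <- coords_matrix(atoms)
  lapply(seq_len(schedule$n_repeats), function(rep_i) {
    set.seed(schedule$seed + 1000L * (rep_i - 1L))
    frames <- lapply(schedule$angles, function(target) {
      delta <- target - base_elbow
      xyz <- xyz0
      if (abs(delta) > 0) {
        R <- rotation_about_axis(n_axis, delta)
        xyz[var_rows, ] <- sweep(sweep(xyz[var_rows, , drop = FALSE], 2, hinge) %*% t(R),
                                 2, hinge, FUN = "+")
      }
      if (schedule$noise_sigma > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = schedule$noise_sigma),
                            ncol = 3)
      }
      xyz
    })
    fab_trajectory(atoms, frames, dt_ns = schedule$dt_ns,
                   repeat_id = paste0("r", rep_i))
  })
}

#' Synthesise a noisy experimental-style SAXS curve from a structure
#'
#' The ground truth is the Debye profile of the structure; Gaussian noise
#' with `sigma(q) = noise_fraction * I(q)` (floored at a small positive
#' value) is added, and the sigma column records the true noise scale, so
#' fitting the truth back against the curve has reduced chi-square near 1.
#'
#' @param atoms Atom table or `fab_structure`.
#' @param q_grid q grid in inverse Angstrom.
#' @param noise_fraction Relative noise level (>= 0).
#' @param seed Integer seed.
#' @param mode,bin_width Forwarded to [debye_profile()].
#' @return A `fab_exp_curve` tibble (`q`, `intensity`, `sigma`) with the
#'   noise-free profile in attribute `truth`.
#' @export
synth_saxs_curve <- function(atoms, q_grid, noise_fraction = 0.02, seed = 1,
                             mode = "residue_cg", bin_width = 0) {
  if (noise_fraction < 0) abort("noise_fraction must be >= 0")
  prof <- debye_profile(atoms, q_grid = q_grid, mode = mode, bin_width = bin_width)
  floor_sigma <- 1e-6 * max(prof$intensity)
  noise_sd <- noise_fraction * prof$intensity
  # reported sigma never hits zero, but no noise is injected beyond noise_sd
  sigma <- pmax(noise_sd, floor_sigma)
  set.seed(seed)
  noisy <- prof$intensity + stats::rnorm(length(noise_sd), sd = noise_sd)
  out <- tibble::tibble(q = prof$q, intensity = noisy, sigma = sigma)
  out <- validate_exp_curve(out)
  attr(out, "truth") <- prof
  out
}

#' Plant known best-fit frames into a trajectory
#'
#' Replaces the listed frames with the target coordinates plus a tiny uniform
#' jitter (at most 0.05 Angstrom per coordinate), producing a trajectory with
#' a known set of best-fitting frames for recovery tests.
#'
#' @param traj A `fab_trajectory`.
#' @param target_coords N x 3 matrix matching the topology.
#' @param frame_ids Distinct frame indices to replace.
#' @param seed Seed for the jitter.
#' @return The modified `fab_trajectory`.
#' @export
plant_best_fit_frames <- function(traj, target_coords, frame_ids, seed = 1) {
  stopifnot(inherits(traj, "fab_trajectory"))
  if (length(frame_ids) == 0) return(traj)
  frame_ids <- as.integer(frame_ids)
  if (anyDuplicated(frame_ids)) abort("duplicate frame ids")
  if (any(frame_ids < 1 | frame_ids > length(traj$frames))) {
    abort("frame ids out of range")
  }
  target_coords <- as.matrix(target_coords)
  if (nrow(target_coords) != nrow(traj$topology)) {
    abort("target coordinates do not match the topology atom count")
  }
  set.seed(seed)
  for (id in frame_ids) {
    jitter <- matrix(stats::runif(length(target_coords), -0.05, 0.05), ncol = 3)
    traj$frames[[id]] <- target_coords + jitter
  }
  traj
}

#' Synthetic stand-ins for the two crystal forms
#'
#' Builds clearly-synthetic Fab-like structures emulating the two crystal
#' forms of the study system: a triclinic-like form with a designed elbow
#' angle of 156 degrees and heavy-chain loop gap of 6 residues, and a
#' hexagonal-like form at 145 degrees with a 4-residue gap; both truncate the
#' heavy chain before the 11-residue C-terminal hinge span (residues
#' 218-228 of a 228-residue full sequence). These are stand-ins built from
#' the printed residue layout, not deposited coordinates, and exist so that
#' the gap-accounting and geometry pipeline can run end to end without
#' downloads.
#'
#' @param form `"triclinic"` (elbow 156 deg, 6-residue gap) or `"hexagonal"`
#'   (elbow 145 deg, 4-residue gap).
#' @param seed Seed for the underlying [build_toy_fab()] call.
#' @return An annotated `fab_structure` with a `seqres` attribute on its atom
#'   table covering the full 228-residue heavy-chain sequence.
#' @export
build_synthetic_crystal_form <- function(form = c("triclinic", "hexagonal"),
                                         seed = 20230928) {
  form <- match.arg(form)
  elbow <- if (form == "triclinic") 156 else 145
  gap_last <- if (form == "triclinic") 137L else 135L
  fab <- build_toy_fab(toy_fab_spec(
    atoms_per_domain = 109, designed_elbow = elbow, seed = seed
  ))
  # heavy chain observed 1..217 minus the flexible CH1 loop 132..gap_last;
  # residue numbering is kept so the dyad correspondence stays exact, and the
  # C-terminal hinge span 218-228 of the 228-residue full sequence is absent
  atoms <- fab$atoms
  drop <- atoms$chain_id == "H" &
    (atoms$residue_number %in% seq.int(132L, gap_last) | atoms$residue_number > 217L)
  atoms <- atoms[!drop, , drop = FALSE]
  atoms$atom_id <- seq_len(nrow(atoms))
  full_h <- paste(aa_three_to_one(synthetic_sequence(228, 0)), collapse = "")
  out <- as_atomset(atoms)
  attr(out, "seqres") <- list(H = full_h)
  attr(out, "space_group") <- if (form == "triclinic") "P 1" else "P 65"
  fab2 <- annotate_fab(out, heavy = "H", light = "L",
                       boundaries = list(VH = c(1L, 109L), VL = c(1L, 109L)))
  for (a in c("designed_elbow", "dyad_variable", "dyad_constant",
              "hinge_point", "module_axis_n")) {
    attr(fab2, a) <- attr(fab, a)
  }
  attr(fab2$atoms, "seqres") <- list(H = full_h)
  attr(fab2$atoms, "space_group") <- attr(out, "space_group")
  fab2
}
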