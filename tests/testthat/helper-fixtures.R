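# shared fixture builders and independent oracles, all generated in code

# minimal atom table of Calpha-style atoms from explicit fields
atoms_fixture <- function(element, chain, resno, xyz, resname = "ALA",
                          atom_name = "CA") {
  as_atomset(data.frame(
    element = element, atom_name = atom_name, residue_name = resname,
    residue_number = resno, chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

# a small peptide with mixed elements for SASA / SAXS oracles
toy_peptide <- function() {
  set.seed(42)
  n_res <- 5
  rows <- list()
  pos <- c(0, 0, 0)
  for (i in seq_len(n_res)) {
    # crude backbone: N, CA, C, O per residue stepping along x
    base <- c(3.5 * (i - 1), 0, 0)
    rows[[i]] <- data.frame(
      element = c("N", "C", "C", "O"),
      atom_name = c("N", "CA", "C", "O"),
      residue_name = c("GLY", "GLY", "GLY", "GLY"),
      residue_number = i, chain_id = "A",
      x = base[1] + c(0, 1.2, 2.2, 2.6),
      y = base[2] + c(0, 1.0, 0.4, -0.7),
      z = base[3] + c(0, 0.3, 1.2, 1.6)
    )
  }
  as_atomset(do.call(rbind, rows))
}

# brute-force superposition oracle: best RMSD over a grid of rotations
# (translation optimal at each step by centroid alignment)
brute_force_min_rmsd <- function(mobile, reference, step_deg = 9) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  ab <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  bb <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a in ab) {
    Ra <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    for (b in bb) {
      Rb <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
      Rab <- Rb %*% Ra
      for (g in ab) {
        Rg <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
        R <- Rg %*% Rab
        r <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
        if (r < best) best <- r
      }
    }
  }
  best
}

# analytic SASA of two intersecting equal spheres of extended radius R at
# centre distance d: per-sphere accessible area = 4 pi R^2 - 2 pi R h,
# h = R - d/2 (height of the buried cap)
two_sphere_sasa_analytic <- function(r_vdw, probe, d) {
  R <- r_vdw + probe
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# global rigid transform applied to every frame of a trajectory
rigidly_move_frames <- function(traj, angle = 25, axis = c(1, 2, 3),
                                shift = c(5, -3, 2)) {
  R <- fablens:::rotation_about_axis(axis, angle)
  traj$frames <- lapply(traj$frames, function(m) {
    sweep(m %*% t(R), 2, shift, FUN = "+")
  })
  traj
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
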