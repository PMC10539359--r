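test_that("Debye profile obeys the q = 0 limit and the two-point closed form", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 25, seed = 1))
  q <- seq(0, 0.3, by = 0.05)
  for (mode in c("atomic", "residue_cg")) {
    p <- debye_profile(fab$atoms, q, mode = mode, bin_width = 0)
    expect_equal(p$intensity[1], attr(p, "total_f")^2, tolerance = 1e-12)
    expect_true(all(p$intensity <= p$intensity[1] + 1e-9))
  }
  # two unit scatterers (hydrogens, f = 1) at separation d
  d <- 10
  two <- atoms_fixture("H", "A", 1:2, cbind(c(0, d), 0, 0))
  p2 <- debye_profile(two, q, mode = "atomic", bin_width = 0)
  closed <- 2 * (1 + ifelse(q == 0, 1, sin(q * d) / (q * d)))
  expect_equal(p2$intensity, closed, tolerance = 1e-12)
  expect_error(debye_profile(two, q, bin_width = -1), "bin_width")
  expect_error(debye_profile(two, c(0.2, 0.1)), "strictly increasing")
})

test_that("distance binning stays within 0.5% of the exact double sum", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 125, seed = 2))
  q <- seq(0.01, 0.3, by = 0.01)
  exact <- debye_profile(fab$atoms, q, mode = "atomic", bin_width = 0)
  binned <- debye_profile(fab$atoms, q, mode = "atomic", bin_width = 0.5)
  expect_lt(max(abs(binned$intensity - exact$intensity) / exact$intensity), 0.005)
})

test_that("the profile is invariant under rigid transforms of the structure", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 30, seed = 3))
  q <- seq(0, 0.25, by = 0.05)
  p1 <- debye_profile(fab$atoms, q, bin_width = 0)
  R <- fablens:::rotation_about_axis(c(1, 4, -1), 51)
  moved <- fablens:::set_coords(
    fab$atoms,
    sweep(fablens:::coords_matrix(fab$atoms) %*% t(R), 2, c(8, 0, -3), FUN = "+"))
  p2 <- debye_profile(moved, q, bin_width = 0)
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-12)
})

test_that("Guinier analysis recovers known radii of gyration", {
  # uniform solid sphere of unit scatterers
  set.seed(4)
  R_sphere <- 25
  pts <- matrix(rnorm(6000), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R_sphere * runif(2000)^(1 / 3)
  sphere <- as_atomset(data.frame(
    element = "H", atom_name = "CA", residue_name = "GLY",
    residue_number = seq_len(2000), chain_id = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  ))
  q <- seq(0.002, 0.08, by = 0.002)
  prof <- debye_profile(sphere, q, mode = "atomic", bin_width = 0.5)
  rg_true <- radius_of_gyration(sphere)
  expect_equal(guinier_rg(prof)$rg, rg_true, tolerance = 0.03)
  expect_equal(rg_true, sqrt(3 / 5) * R_sphere, tolerance = 0.02)
  # two equal point scatterers: Rg = d/2
  two <- atoms_fixture("H", "A", 1:2, cbind(c(0, 20), 0, 0))
  p2 <- debye_profile(two, seq(0.002, 0.06, by = 0.002), bin_width = 0)
  expect_equal(guinier_rg(p2)$rg, 10, tolerance = 0.03 * 10)
  short <- debye_profile(two, c(0.001, 0.002, 0.003, 0.004), bin_width = 0)
  expect_error(guinier_rg(short), ">= 5")
})

test_that("Guinier Rg agrees with coordinate Rg on a compact toy", {
  set.seed(5)
  pts <- matrix(rnorm(900, sd = 8), ncol = 3)
  blob <- atoms_fixture("C", "A", seq_len(300), pts)
  q <- seq(0.001, 0.1, by = 0.002)
  prof <- debye_profile(blob, q, mode = "atomic", bin_width = 0)
  expect_equal(guinier_rg(prof)$rg, radius_of_gyration(blob),
               tolerance = 0.05)
})

test_that("chi-square fitting recovers scale and is scale-invariant", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 25, seed = 6))
  q <- seq(0.01, 0.3, by = 0.01)
  calc <- debye_profile(fab$atoms, q, bin_width = 0)
  selfexp <- tibble::tibble(q = q, intensity = calc$intensity, sigma = 1)
  fit <- chi_square_fit(calc, selfexp)
  expect_equal(fit$chi_square, 0, tolerance = 1e-15)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  doubled <- tibble::tibble(q = q, intensity = 2 * calc$intensity, sigma = 1)
  fit2 <- chi_square_fit(calc, doubled)
  expect_equal(fit2$chi_square, 0, tolerance = 1e-15)
  expect_equal(fit2$scale, 2, tolerance = 1e-12)
  # multiplying the calculated curve by any constant changes nothing
  noisy <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0.05, seed = 1,
                            bin_width = 0)
  f_a <- chi_square_fit(calc, noisy)
  calc_scaled <- calc
  calc_scaled$intensity <- calc$intensity * 37.5
  f_b <- chi_square_fit(calc_scaled, noisy)
  expect_equal(f_a$chi_square, f_b$chi_square, tolerance = 1e-9)
  expect_equal(f_b$scale, f_a$scale / 37.5, tolerance = 1e-9)
})

test_that("reduced chi-square is near 1 when fitting truth against its own noise model", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 25, seed = 7))
  q <- seq(0.01, 0.3, by = 0.005)
  truth <- debye_profile(fab$atoms, q, mode = "residue_cg", bin_width = 0)
  chis <- vapply(1:50, function(s) {
    curve <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0.02, seed = s,
                              mode = "residue_cg", bin_width = 0)
    chi_square_fit(truth, curve)$chi_square
  }, numeric(1))
  expect_equal(mean(chis), 1, tolerance = 0.1)
})

test_that("per-frame fitting finds a planted optimum", {
  fab <- build_toy_fab(toy_fab_spec(designed_elbow = 150, atoms_per_domain = 25,
                                    seed = 8))
  sched <- seq(160, 130, length.out = 21)
  sched[13] <- 150 # the generator pose itself
  traj <- make_hinge_trajectory(fab, hinge_schedule(sched))[[1]]
  q <- seq(0.01, 0.25, by = 0.01)
  exp_curve <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0, seed = 1,
                                mode = "residue_cg", bin_width = 0.5)
  fits <- fit_trajectory(traj, exp_curve, bin_width = 0.5)
  expect_equal(which.min(fits$chi_square), 13)
  expect_lt(min(fits$chi_square), 1e-6)
  expect_false(any(fits$failed))
  # identical frames give a constant series
  static <- make_hinge_trajectory(fab, hinge_schedule(rep(150, 4)))[[1]]
  fs <- fit_trajectory(static, exp_curve, bin_width = 0.5)
  expect_equal(length(unique(round(fs$chi_square, 9))), 1)
})

test_that("top-N extraction selects, orders and tie-breaks frames correctly", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 20, seed = 9))
  traj <- make_hinge_trajectory(fab, hinge_schedule(rep(150, 6)))[[1]]
  fits <- tibble::tibble(
    frame = 1:6, time_ns = (0:5) / 10,
    chi_square = c(5, 1, 3, 1, 2, 6), scale = 1,
    rg = 20, repeat_id = "r1", failed = FALSE
  )
  top <- top_n_frames(fits, traj, n = 3)
  expect_equal(top$frames$chi_square, c(1, 1, 2))
  # the tie at chi-square 1 resolves to the earlier frame first
  expect_equal(top$frames$frame[1:2], c(2, 4))
  expect_equal(dim(top$rmsd_matrix), c(3, 3))
  expect_true(all(top$rmsd_matrix[upper.tri(top$rmsd_matrix)] < 1e-6))
  expect_error(top_n_frames(fits, traj, n = 10), "need 10")
})

test_that("planted best-fit frames are recovered from a larger ensemble", {
  fab <- build_toy_fab(toy_fab_spec(designed_elbow = 150, atoms_per_domain = 20,
                                    seed = 10))
  sched <- seq(170, 120, length.out = 100)
  traj <- make_hinge_trajectory(fab, hinge_schedule(sched, noise_sigma = 0.3,
                                                    seed = 11))[[1]]
  planted <- c(7, 19, 33, 58, 91)
  traj <- plant_best_fit_frames(traj, fablens:::coords_matrix(fab$atoms),
                                planted, seed = 12)
  q <- seq(0.01, 0.25, by = 0.01)
  exp_curve <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0, seed = 2,
                                mode = "residue_cg", bin_width = 0.5)
  fits <- fit_trajectory(traj, exp_curve, bin_width = 0.5)
  top <- top_n_frames(fits, traj, n = 5)
  expect_setequal(top$frames$frame, planted)
  expect_error(plant_best_fit_frames(traj, fablens:::coords_matrix(fab$atoms),
                                     c(3, 3)), "duplicate")
  expect_error(plant_best_fit_frames(traj, fablens:::coords_matrix(fab$atoms),
                                     1000), "out of range")
  unchanged <- plant_best_fit_frames(traj, fablens:::coords_matrix(fab$atoms),
                                     integer(0))
  expect_identical(unchanged$frames, traj$frames)
})

test_that("SAXS curve text round-trip and unit conversion work", {
  tmp <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "# synthetic curve",
    "0.01  1000.0  10.0",
    "0.02, 950.0, 9.5",
    "0.03  900.0  9.0",
    "0.04  850.0  8.5",
    "0.05  800.0  8.0"
  ), tmp)
  cur <- read_saxs_curve(tmp)
  expect_equal(nrow(cur), 5)
  expect_equal(cur$q[2], 0.02)
  nm <- read_saxs_curve(tmp, q_units = "nm^-1")
  expect_equal(nm$q, cur$q / 10)
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines("0.01 1000", bad)
  expect_error(read_saxs_curve(bad), "3 columns")
})

test_that("synthetic curves are deterministic and exact at zero noise", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 20, seed = 13))
  q <- seq(0.01, 0.2, by = 0.01)
  clean <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0, seed = 5, bin_width = 0)
  expect_equal(clean$intensity, attr(clean, "truth")$intensity)
  a <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0.03, seed = 6, bin_width = 0)
  b <- synth_saxs_curve(fab$atoms, q, noise_fraction = 0.03, seed = 6, bin_width = 0)
  expect_identical(a$intensity, b$intensity)
  expect_error(synth_saxs_curve(fab$atoms, q, noise_fraction = -0.1), "noise_fraction")
})
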