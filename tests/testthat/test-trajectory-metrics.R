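test_that("trajectory construction validates atom counts and time step", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 20, seed = 1))
  xyz <- fablens:::coords_matrix(fab$atoms)
  expect_s3_class(fab_trajectory(fab$atoms, list(xyz, xyz), dt_ns = 0.1),
                  "fab_trajectory")
  expect_error(fab_trajectory(fab$atoms, list(xyz[-1, ]), dt_ns = 0.1),
               "atom count")
  expect_error(fab_trajectory(fab$atoms, list(xyz), dt_ns = 0), "dt_ns")
})

test_that("multi-model PDB trajectories read back frame by frame and concatenate", {
  fab <- build_toy_fab(toy_fab_spec(atoms_per_domain = 20, seed = 2))
  traj <- make_hinge_trajectory(fab, hinge_schedule(seq(150, 148, length.out = 5)))[[1]]
  top <- withr::local_tempfile(fileext = ".pdb")
  t1 <- withr::local_tempfile(fileext = ".pdb")
  t2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fab$atoms, top)
  write_structure(fab$atoms, t1, frames = traj$frames)
  write_structure(fab$atoms, t2, frames = traj$frames[1:3])
  rt <- read_trajectory(top, t1, dt_ns = 0.1)
  expect_equal(length(rt$frames), 5)
  expect_lt(max(abs(rt$frames[[3]] - traj$frames[[3]])), 5.1e-4)
  both <- read_trajectory(top, c(t1, t2), dt_ns = 0.1)
  expect_equal(length(both$frames), 8)
  expect_lt(max(abs(both$frames[[6]] - traj$frames[[1]])), 5.1e-4)
  # mismatched topology
  small <- build_toy_fab(toy_fab_spec(atoms_per_domain = 21, seed = 2))
  top2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(small$atoms, top2)
  expect_error(read_trajectory(top2, t1, dt_ns = 0.1), "mismatch")
  expect_error(read_trajectory(top, "traj.xtc", dt_ns = 0.1), "XTC")
})

test_that("radius of gyration matches closed forms", {
  single <- atoms_fixture("C", "A", 1, cbind(3, -2, 8))
  expect_equal(radius_of_gyration(single), 0)
  pair <- atoms_fixture("C", "A", 1:2, cbind(c(0, 2), 0, 0))
  expect_equal(radius_of_gyration(pair), 1.0, tolerance = 1e-12)
  # uniform solid sphere: Rg = sqrt(3/5) R
  set.seed(21)
  R_sphere <- 30
  pts <- matrix(rnorm(3e5), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R_sphere * runif(1e5)^(1 / 3)
  unif <- as_atomset(data.frame(
    element = "C", atom_name = "CA", residue_name = "GLY",
    residue_number = seq_len(1e5), chain_id = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  ))
  expect_equal(radius_of_gyration(unif), sqrt(3 / 5) * R_sphere, tolerance = 0.01)
})

test_that("Rg series is constant for static frames and homogeneous under dilation", {
  fab <- build_toy_fab(toy_fab_spec(seed = 3))
  static <- make_hinge_trajectory(fab, hinge_schedule(rep(150, 4)))[[1]]
  rg <- rg_timeseries(static)
  expect_equal(length(unique(round(rg$rg, 9))), 1)
  expect_equal(rg$rg_nm, rg$rg / 10)
  scaled <- static
  scaled$frames <- lapply(static$frames, function(m) m * 1.7)
  expect_equal(rg_timeseries(scaled)$rg, rg$rg * 1.7, tolerance = 1e-9)
})

test_that("hinge opening strictly increases Rg", {
  fab <- build_toy_fab(toy_fab_spec(designed_elbow = 120, seed = 4))
  open <- make_hinge_trajectory(fab, hinge_schedule(seq(120, 175, length.out = 12)))[[1]]
  rg <- rg_timeseries(open)$rg
  expect_true(all(diff(rg) > 0))
})

test_that("RMSD to start is zero for static or rigidly moved frames", {
  fab <- build_toy_fab(toy_fab_spec(seed = 5))
  static <- make_hinge_trajectory(fab, hinge_schedule(rep(150, 5)))[[1]]
  expect_true(all(rmsd_to_start(static)$rmsd < 1e-9))
  moved <- static
  for (i in seq_along(moved$frames)) {
    R <- fablens:::rotation_about_axis(c(i, 1, 0), 10 * i)
    moved$frames[[i]] <- sweep(moved$frames[[i]] %*% t(R), 2, c(0, i, 0), FUN = "+")
  }
  expect_true(all(rmsd_to_start(moved)$rmsd < 1e-6))
})

test_that("RMSD series under noise matches a direct per-frame recomputation", {
  fab <- build_toy_fab(toy_fab_spec(seed = 6))
  noisy <- make_hinge_trajectory(
    fab, hinge_schedule(rep(150, 30), noise_sigma = 0.25, seed = 7))[[1]]
  out <- rmsd_to_start(noisy)
  idx <- which(noisy$topology$atom_name == "CA")
  ref <- noisy$frames[[1]][idx, ]
  direct <- vapply(noisy$frames, function(m) {
    fit <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(m[idx, ])),
                          fixed.inds = seq_len(3 * nrow(ref)),
                          mobile.inds = seq_len(3 * nrow(ref)))
    sqrt(mean(colSums(matrix((fit - as.vector(t(ref)))^2, nrow = 3))))
  }, numeric(1))
  expect_equal(out$rmsd, direct, tolerance = 1e-6)
  # noise in both reference and frame: plateau near sigma*sqrt(3)*sqrt(2)
  expect_equal(mean(out$rmsd[-1]), 0.25 * sqrt(3) * sqrt(2), tolerance = 0.1)
})

test_that("repeat aggregation reproduces pointwise formulas", {
  mk <- function(vals) tibble::tibble(time_ns = seq_along(vals) - 1, rg = vals)
  same <- replicate(4, mk(c(1, 2, 3)), simplify = FALSE)
  agg <- aggregate_repeats(same)
  expect_equal(agg$sem, rep(0, 3))
  expect_equal(agg$mean, c(1, 2, 3))
  a <- c(1, 5, 9); b <- c(3, 1, 5)
  agg2 <- aggregate_repeats(list(mk(a), mk(b)))
  expect_equal(agg2$mean, (a + b) / 2)
  expect_equal(agg2$sem, abs(a - b) / 2)
  expect_equal(agg2$n_repeats, rep(2, 3))
  shifted <- mk(a); shifted$time_ns <- shifted$time_ns + 0.5
  expect_error(aggregate_repeats(list(mk(a), shifted)), "common time grid")
  # mean column equals an independently recomputed arithmetic mean, exactly
  set.seed(8)
  reps <- replicate(6, mk(rnorm(20)), simplify = FALSE)
  agg3 <- aggregate_repeats(reps)
  manual <- rowMeans(vapply(reps, function(s) s$rg, numeric(20)))
  expect_equal(agg3$mean, manual, tolerance = 1e-15)
  sd6 <- apply(vapply(reps, function(s) s$rg, numeric(20)), 1, sd)
  expect_equal(agg3$sem, sd6 / sqrt(6))
})

test_that("hydrogen bond detection applies distance and angle criteria", {
  mk_hbond_system <- function(d_ho = 1.95, angle_deg = 165) {
    th <- (180 - angle_deg) * pi / 180
    o_pos <- c(1 + d_ho * cos(th), d_ho * sin(th), 0)
    as_atomset(data.frame(
      element = c("N", "H", "O", "C"),
      atom_name = c("N", "H1", "O", "CA"),
      residue_name = c("GLY", "GLY", "GLY", "GLY"),
      residue_number = c(1, 1, 50, 50),
      chain_id = c("H", "H", "L", "L"),
      x = c(0, 1, o_pos[1], o_pos[1] + 1.5),
      y = c(0, 0, o_pos[2], o_pos[2]),
      z = 0
    ))
  }
  fab <- function(atoms) structure(list(atoms = atoms, heavy_chain = "H",
                                        light_chain = "L",
                                        domain_ranges = list()),
                                   class = "fab_structure")
  good <- interchain_hbonds(fab(mk_hbond_system()))
  expect_equal(nrow(good), 1)
  expect_lt(abs(good$distance - 2.93), 0.05)
  far <- interchain_hbonds(fab(mk_hbond_system(d_ho = 3.3)))
  expect_equal(nrow(far), 0)
  bent <- interchain_hbonds(fab(mk_hbond_system(angle_deg = 95)))
  expect_equal(nrow(bent), 0)
  # without hydrogens only the distance criterion applies
  no_h <- mk_hbond_system()
  no_h <- no_h[no_h$element != "H", ]
  expect_equal(nrow(interchain_hbonds(fab(no_h))), 1)
})
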