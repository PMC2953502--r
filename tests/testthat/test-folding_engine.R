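# The optimization-simulation folding loop

test_that("extended initial chains have 3.8 A bonds and no non-covalent contacts", {
  native <- make_fixture("helix_hairpin", 20)
  init <- make_initial_chain(native, folding_config(init_mode = "extended"))
  bonds <- sqrt(rowSums(diff(init$coords)^2))
  expect_equal(bonds, rep(3.8, 19))
  expect_equal(sqrt(sum((init$coords[3, ] - init$coords[1, ])^2)), 7.6)
  cm <- compute_contact_map(init, 7)
  expect_true(all(cm$pairs[, 2] - cm$pairs[, 1] == 1L))
  # centroid aligned with the native centroid
  expect_equal(colMeans(init$coords), colMeans(native$coords))
})

test_that("scaled_native with factor 1 is the native chain itself", {
  native <- make_fixture("ideal_helix", 12)
  cfg <- folding_config(init_mode = "scaled_native", scale_factor = 1)
  init <- make_initial_chain(native, cfg)
  expect_equal(init$coords, native$coords)
  traj <- quiet_run(native, cfg)
  expect_true(traj$converged)
  expect_lte(traj$cycles_used, 1L)
})

test_that("random_coil is reproducible per seed, self-avoiding and leaves the RNG alone", {
  native <- make_fixture("helix_hairpin", 20)
  cfg <- folding_config(init_mode = "random_coil", seed = 5)
  set.seed(999); before <- stats::runif(1)
  a <- make_initial_chain(native, cfg)
  b <- make_initial_chain(native, cfg)
  expect_identical(a$coords, b$coords)
  d <- as.matrix(stats::dist(a$coords))
  sep <- abs(row(d) - col(d))
  expect_gte(min(d[sep > 1 & upper.tri(d)]), 3.5)
  expect_equal(sqrt(rowSums(diff(a$coords)^2)), rep(3.8, 19))
  c2 <- make_initial_chain(native, folding_config(init_mode = "random_coil",
                                                  seed = 6))
  expect_false(identical(a$coords, c2$coords))
  set.seed(999)
  expect_identical(stats::runif(1), before)  # caller RNG untouched
})

test_that("simulate_segment reproduces the matrix exponential exactly", {
  # native start is a fixed point
  A <- -diag(c(1, 2, 3))
  z <- simulate_segment(A, matrix(0, 3, 3), 1, 0.25)
  expect_true(all(vapply(z$states, function(s) all(s == 0), logical(1))))
  # closed form for a decoupled mode: x(1) = exp(-2)
  s <- simulate_segment(A, c(0, 1, 0), 1, 0.5)
  expect_equal(s$states[[2]][2, 1], exp(-2), tolerance = 1e-12)
  expect_equal(s$times, c(0.5, 1))
  # norm decay is monotone for symmetric negative-definite dynamics
  set.seed(3)
  M <- crossprod(matrix(stats::rnorm(25), 5))
  A5 <- -(M + 0.1 * diag(5))
  seg <- simulate_segment(A5, stats::rnorm(5), 2, 0.1)
  norms <- vapply(seg$states, function(s) sqrt(sum(s^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("a native extended start is already converged", {
  native <- make_fixture("extended", 10)
  traj <- quiet_run(native, folding_config(init_mode = "extended"))
  expect_true(traj$converged)
  expect_lte(traj$cycles_used, 1L)
  expect_equal(length(traj$contact_maps), traj$cycles_used)
})

test_that("the hairpin folds from an extended start to the exact native map", {
  native <- make_fixture("helix_hairpin", 20)
  traj <- quiet_run(native, folding_config())
  expect_true(traj$converged)
  final <- conformation_at(traj, length(traj$times))
  expect_true(contact_maps_equal(compute_contact_map(final, 7),
                                 compute_contact_map(native, 7)))
  expect_lte(chain_rmsd(final, native), 0.5)
  # deviation norm decreases monotonically along the whole run
  norms <- vapply(traj$states, function(s) sqrt(sum(s^2)), numeric(1))
  expect_true(all(diff(norms) < 1e-12))
})

test_that("larger alpha slows the approach to the native state", {
  native <- make_fixture("helix_hairpin", 20)
  half_time <- function(alpha) {
    traj <- quiet_run(native, folding_config(alpha = alpha, max_cycles = 150))
    rmsd <- vapply(traj$states, function(s) sqrt(mean(rowSums(s^2))), numeric(1))
    traj$times[which(rmsd <= rmsd[1] / 2)[1]]
  }
  t1 <- half_time(1); t10 <- half_time(10)
  expect_lt(t1, t10)
})

test_that("identical config and seed give bit-identical trajectories", {
  native <- make_fixture("helix_hairpin", 20)
  cfg <- folding_config(init_mode = "random_coil", seed = 11, max_cycles = 60)
  t1 <- quiet_run(native, cfg)
  t2 <- quiet_run(native, cfg)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  expect_identical(contact_events(t1), contact_events(t2))
})

test_that("non-convergence returns a trajectory with a warning, not an error", {
  native <- make_fixture("helix_hairpin", 20)
  expect_warning(
    traj <- suppressMessages(run_folding(native, folding_config(max_cycles = 2))),
    "did not converge")
  expect_false(traj$converged)
  expect_equal(traj$cycles_used, 2L)
})

test_that("trajectory CSV export has one row per time per residue", {
  native <- make_fixture("ideal_helix", 10)
  traj <- suppressWarnings(
    quiet_run(native, folding_config(max_cycles = 3, t_sample = 0.5,
                                     init_mode = "scaled_native")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), length(traj$times) * 10L)
  expect_equal(df$x[df$time == 0], unname(traj$initial$coords[, 1]))
})
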