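# Folding observables

# a tiny handmade trajectory: native square-ish chain, one deviated frame
fake_trajectory <- function(native_coords, state_list, times,
                            cutoff = 7, cfg = folding_config(cutoff = cutoff)) {
  native <- chain(native_coords, label = "handmade")
  structure(list(times = times, states = state_list,
                 contact_maps = list(), gains = list(),
                 cycle_start = numeric(0), converged = TRUE, cycles_used = 0L,
                 native = native, initial = native, config = cfg),
            class = "folding_trajectory")
}

test_that("f equals 1 on the native conformation and 0 for unformed clusters", {
  native <- make_fixture("helix_hairpin", 20)
  nm <- compute_contact_map(native, 7)
  h <- (20 - 4) %/% 2
  inter <- cluster_definition("inter", 1:h, (h + 5):20, nm)
  helixA <- cluster_definition("H1", 1:h, 1:h, nm)
  traj <- quiet_run(native, folding_config(init_mode = "scaled_native",
                                           scale_factor = 1))
  # degenerate native-start run records only t = 0; extend it by hand
  traj$times <- c(0, 1)
  traj$states <- list(traj$states[[1]], traj$states[[1]])
  for (cl in list(inter, helixA))
    expect_true(all(fraction_contacts(traj, cl)$f == 1))
  # extended start: non-local cluster completely unformed
  init <- make_initial_chain(native, folding_config())
  traj0 <- fake_trajectory(native$coords,
                           list(init$coords - native$coords,
                                init$coords - native$coords), c(0, 1))
  expect_true(all(fraction_contacts(traj0, inter)$f == 0))
})

test_that("f counts non-native pairs in the region and can exceed 1", {
  # native: pairs (1,3) and (1,4) in contact, (2,4) not; deviated frame
  # brings 2-4 within the cutoff as a non-native contact -> f = 3/2
  nat <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(2, 3.2, 0), c(0.5, 6.7, 0),
               c(4.3, 6.7, 0), c(8.1, 6.7, 0))
  x1 <- rbind(0, c(-1.5, 1.5, 0), 0, 0, 0, 0)
  traj <- fake_trajectory(nat, list(matrix(0, 6, 3), x1), c(0, 1))
  nm <- compute_contact_map(traj$native, 7)
  cl <- cluster_definition("T", 1:2, 3:4, nm)
  expect_equal(nrow(cl$native_pairs), 2L)
  f <- fraction_contacts(traj, cl)$f
  expect_equal(f[2], 1.5)
  # native-only mode never exceeds 1
  expect_lte(max(fraction_contacts(traj, cl, native_only = TRUE)$f), 1)
  # empty region is refused
  expect_error(cluster_definition("E", 5:6, 5:6, nm), "empty cluster")
})

test_that("contact events record grid-resolved initiation and completion", {
  nat <- make_fixture("helix_hairpin", 20)
  # native-start: every native pair initiates at t = 0
  ns <- fake_trajectory(nat$coords, list(matrix(0, 20, 3), matrix(0, 20, 3)),
                        c(0, 1))
  ev <- contact_events(ns)
  nm <- compute_contact_map(nat, 7)
  noncov <- nm$pairs[nm$pairs[, 2] - nm$pairs[, 1] > 1, , drop = FALSE]
  expect_setequal(paste(ev$i, ev$j), paste(noncov[, 1], noncov[, 2]))
  expect_true(all(ev$t_init == 0))
  expect_true(all(ev$is_native))
  # a pair that forms, breaks, and re-forms completes later than it initiates
  base <- make_fixture("extended", 5)$coords
  near <- base; near[5, ] <- base[1, ] + c(0, 5, 0)       # (1,5) formed
  far <- base
  tr <- fake_trajectory(base, list(base - base, near - base, far - base,
                                   near - base), c(0, 1, 2, 3))
  ev2 <- contact_events(tr)
  row <- ev2[ev2$i == 1 & ev2$j == 5, ]
  expect_equal(row$t_init, 1)
  expect_equal(row$t_complete, 3)
  expect_gt(row$t_complete, row$t_init)
  # on a converged run the native-pair events are exactly the native set
  traj <- quiet_run(nat, folding_config())
  evn <- contact_events(traj)
  expect_setequal(paste(evn$i[evn$is_native], evn$j[evn$is_native]),
                  paste(noncov[, 1], noncov[, 2]))
})

test_that("radius of gyration follows its definition and invariances", {
  expect_equal(radius_of_gyration(matrix(1, 4, 3)), 0)
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)        # d/2 for a pair
  ch <- make_fixture("ideal_helix", 15)
  rg <- radius_of_gyration(ch)
  rot <- ch$coords %*% matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  expect_equal(radius_of_gyration(sweep(rot, 2, c(5, -2, 1))), rg)
  expect_equal(radius_of_gyration(2.5 * ch$coords), 2.5 * rg)
  # along a converged run Rg approaches the native value
  native <- make_fixture("helix_hairpin", 20)
  traj <- quiet_run(native, folding_config())
  rgs <- rg_series(traj)
  expect_lt(abs(rgs$rg[nrow(rgs)] - radius_of_gyration(native)), 0.5)
})

test_that("pair distance series start from the construction geometry", {
  native <- make_fixture("helix_hairpin", 20)
  traj <- quiet_run(native, folding_config())
  # covalent neighbours on the extended start begin at 3.8 A
  s <- pair_distance_series(traj, 4, 5)
  expect_equal(s$distance[1], 3.8)
  # any native contact pair ends within the cutoff on a converged run
  nm <- compute_contact_map(native, 7)
  for (r in sample(nrow(nm$pairs), 5)) {
    p <- nm$pairs[r, ]
    d <- pair_distance_series(traj, p[1], p[2])$distance
    expect_lte(d[length(d)], 7)
  }
  expect_error(pair_distance_series(traj, 0, 5), "out of range")
  expect_error(pair_distance_series(traj, 3, 3), "out of range")
})

test_that("instantaneous cost terms integrate to the Lyapunov closed form", {
  native <- make_fixture("ideal_helix", 8)
  cfg <- folding_config(dt_record = 0.002, t_sample = 1, max_cycles = 1,
                        init_mode = "scaled_native", scale_factor = 1.8)
  traj <- suppressWarnings(quiet_run(native, cfg))
  cd <- cost_decay_series(traj)
  g <- traj$gains[[1]]
  gamma <- connectivity_matrix(compute_contact_map(traj$initial, 7), 1)
  A_cl <- closed_loop_matrix(gamma, g, 1)
  x0 <- traj$states[[1]]
  xT <- traj$states[[length(traj$states)]]
  # segment integral = difference of the infinite-horizon quadratic forms
  cf0 <- lqr_cost_integrals(A_cl, g, g$Q, alpha = 1, x0 = x0)
  cfT <- lqr_cost_integrals(A_cl, g, g$Q, alpha = 1, x0 = xT)
  trap <- function(y) sum(diff(cd$time) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(cd$state_term), cf0$state_cost - cfT$state_cost,
               tolerance = 0.01)
  expect_equal(trap(cd$control_term), cf0$control_cost - cfT$control_cost,
               tolerance = 0.01)
  # both terms decay on a converged run
  native2 <- make_fixture("helix_hairpin", 20)
  traj2 <- quiet_run(native2, folding_config())
  cd2 <- cost_decay_series(traj2)
  expect_lt(cd2$state_term[nrow(cd2)], 0.01 * cd2$state_term[1])
  expect_lt(cd2$control_term[nrow(cd2)], 0.05 * cd2$control_term[1])
})

test_that("ECO is the shortest loop-closure path and shrinks as contacts form", {
  expect_equal(effective_contact_order(2, 9, NULL, 10), 7L)  # plain CO
  expect_equal(effective_contact_order(1, 10, cbind(3, 8), 10), 5L)
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    formed <- random_contact_map(n, p = 0.25)$pairs
    formed <- formed[formed[, 2] - formed[, 1] > 1, , drop = FALSE]
    i <- sample(n - 1, 1)
    j <- if (i + 1L == n) n else sample((i + 1):n, 1)
    edges <- rbind(cbind(1:(n - 1), 2:n), formed)
    expect_equal(effective_contact_order(i, j, formed, n),
                 exhaustive_shortest_path(i, j, edges, n))
    # adding one more contact never increases the ECO
    extra <- rbind(formed, c(1L, n))
    expect_lte(effective_contact_order(i, j, extra, n),
               effective_contact_order(i, j, formed, n))
  }
})
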