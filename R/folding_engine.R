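# The learning optimal-control loop: simulate the closed loop, re-measure
# contacts, rebuild Q, re-synthesize the gain, repeat until the dynamic
# contact map converges to the native map.

#' Configuration of a folding run
#'
#' All times are in the model's dimensionless units (friction and spring
#' constant default to 1).
#'
#' @param cutoff contact cutoff in Angstrom.
#' @param alpha LQR trade-off scalar; larger values penalize entropy loss
#'   more and slow folding.
#' @param epsilon ridge of the state weight Q; sets the native-anchor spring
#'   `k = sqrt(epsilon / alpha)`.
#' @param beta friction coefficient.
#' @param spring_constant Gaussian-network spring constant.
#' @param t_sample duration of one optimization-simulation cycle: the
#'   interval after which contacts are re-measured and the gain re-synthesized.
#' @param dt_record spacing of the recording grid within a cycle; must not
#'   exceed `t_sample`.
#' @param rmsd_tol convergence tolerance on the RMSD to the native state, Angstrom.
#' @param max_cycles cycle budget; non-convergence within it is reported via
#'   a warning, never an error.
#' @param init_mode initial conformation: `"extended"` (straight chain,
#'   3.8 A virtual bonds), `"scaled_native"` (native dilated about its
#'   centroid) or `"random_coil"` (seeded self-avoiding-ish walk).
#' @param scale_factor dilation factor for `scaled_native` (default 2.5, at
#'   which only covalent contacts survive a 7 A cutoff for typical folds).
#' @param seed integer seed, used only by `random_coil`.
#' @param update_gamma if `TRUE`, rebuild the connectivity matrix Gamma from
#'   the current conformation each cycle (sensitivity studies); by default
#'   Gamma is frozen at the initial structure and the dynamic contact map
#'   enters only through Q.
#' @param clash_dist excluded-volume diagnostic distance: non-bonded pairs
#'   closer than this are logged (not prevented) at each cycle end.
#' @return an object of class `folding_config`.
#' @export
folding_config <- function(cutoff = 7, alpha = 1, epsilon = 0.01, beta = 1,
                           spring_constant = 1, t_sample = 1, dt_record = 0.1,
                           rmsd_tol = 0.5, max_cycles = 200L,
                           init_mode = c("extended", "scaled_native", "random_coil"),
                           scale_factor = 2.5, seed = 1L,
                           update_gamma = FALSE, clash_dist = 2.0) {
  init_mode <- match.arg(init_mode)
  num <- c(cutoff = cutoff, alpha = alpha, epsilon = epsilon, beta = beta,
           spring_constant = spring_constant, t_sample = t_sample,
           dt_record = dt_record, rmsd_tol = rmsd_tol, scale_factor = scale_factor,
           clash_dist = clash_dist)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all numeric configuration values must be positive; offending: ",
         paste(names(num)[!is.finite(num) | num <= 0], collapse = ", "))
  if (dt_record > t_sample) stop("dt_record must not exceed t_sample")
  if (max_cycles < 1L) stop("max_cycles must be at least 1")
  structure(
    list(cutoff = cutoff, alpha = alpha, epsilon = epsilon, beta = beta,
         spring_constant = spring_constant, t_sample = t_sample,
         dt_record = dt_record, rmsd_tol = rmsd_tol,
         max_cycles = as.integer(max_cycles), init_mode = init_mode,
         scale_factor = scale_factor, seed = as.integer(seed),
         update_gamma = isTRUE(update_gamma), clash_dist = clash_dist),
    class = "folding_config")
}

#' Construct an initial (unfolded) conformation
#'
#' @param native the native [chain()].
#' @param config a [folding_config()]; `init_mode`, `scale_factor` and
#'   `seed` are used.
#' @return a [chain()] with the same residue count as `native`, centroid
#'   aligned to the native centroid.
#' @export
make_initial_chain <- function(native, config = folding_config()) {
  stopifnot(inherits(native, "chain"), inherits(config, "folding_config"))
  n <- native$n
  ctr <- colMeans(native$coords)
  coords <- switch(config$init_mode,
    extended = {
      x <- cbind(3.8 * (seq_len(n) - (n + 1) / 2), 0, 0)
      sweep(x, 2L, -ctr)
    },
    scaled_native = {
      dev <- sweep(native$coords, 2L, ctr)
      sweep(config$scale_factor * dev, 2L, -ctr)
    },
    random_coil = random_coil_coords(n, config$seed, ctr))
  chain(coords, label = paste0(native$label, ":", config$init_mode),
        pdb_resno = native$pdb_resno, resid = native$resid)
}

# Seeded self-avoiding-ish walk: 3.8 A steps, beads kept >= 3.5 A apart,
# bounded retries. RNG state of the caller is left untouched.
random_coil_coords <- function(n, seed, ctr, min_sep = 3.5,
                               max_tries = 200L, max_restarts = 25L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  for (restart in seq_len(max_restarts)) {
    coords <- matrix(0, n, 3L)
    ok <- TRUE
    for (i in 2L:n) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- stats::rnorm(3L)
        cand <- coords[i - 1L, ] + 3.8 * u / sqrt(sum(u^2))
        if (i == 2L ||
            min(sqrt(rowSums(sweep(coords[seq_len(i - 2L), , drop = FALSE],
                                   2L, cand)^2))) >= min_sep) {
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(sweep(coords, 2L, colMeans(coords) - ctr))
  }
  stop("random_coil placement failed after bounded retries; try another seed")
}

#' Propagate closed-loop dynamics over one segment
#'
#' The per-axis dynamics `dx/dt = A_cl x` are linear, so states on the
#' recording grid are computed exactly (to floating point) through the
#' matrix exponential, here via the spectral decomposition of the symmetric
#' stable `A_cl`.
#'
#' @param A_cl symmetric stable closed-loop matrix.
#' @param x0 n x 3 deviation matrix (or length-n vector) at segment start.
#' @param duration segment length in time units.
#' @param dt_record recording grid spacing.
#' @return list with `times` (not including 0) and `states` (list of
#'   deviation matrices, one per time).
#' @export
simulate_segment <- function(A_cl, x0, duration, dt_record) {
  A_cl <- as.matrix(A_cl)
  if (!isSymmetric(A_cl, tol = 1e-9)) stop("A_cl must be symmetric")
  x0 <- if (is.matrix(x0)) x0 else matrix(x0, ncol = 1L)
  e <- eigen((A_cl + t(A_cl)) / 2, symmetric = TRUE)
  if (max(e$values) >= 0) stop("A_cl must be stable")
  times <- seq(dt_record, duration, by = dt_record)
  if (length(times) == 0L || times[length(times)] < duration - 1e-12)
    times <- c(times, duration)
  y0 <- crossprod(e$vectors, x0)       # modal coordinates
  states <- lapply(times, function(t)
    e$vectors %*% (exp(e$values * t) * y0))
  list(times = times, states = states)
}

#' Run the learning optimal-control folding loop
#'
#' One cycle: (1) measure the contact map of the current conformation;
#' (2) rebuild `Q` from it; (3) re-synthesize the optimal gain by solving
#' the Riccati equation; (4) form the closed-loop network with the
#' connectivity matrix Gamma of the *initial* structure (unless
#' `update_gamma`); (5) propagate the deviations for `t_sample`;
#' (6) update the conformation `R = R_native + x`. The loop stops when the
#' dynamic contact map equals the native map (exact set equality) and the
#' RMSD to the native state is at or below `rmsd_tol`, or when `max_cycles`
#' is exhausted (then `converged = FALSE` with a warning).
#'
#' @param native the native [chain()]; its contact graph must be connected
#'   at the chosen cutoff.
#' @param config a [folding_config()].
#' @return an object of class `folding_trajectory`: `times` (recording
#'   grid, starting at 0), `states` (deviation matrices per time),
#'   `contact_maps`, `gains` and `cycle_start` (per cycle), `converged`,
#'   `cycles_used`, `clashes` (excluded-volume log), plus the native chain,
#'   initial chain and config.
#' @export
run_folding <- function(native, config = folding_config()) {
  stopifnot(inherits(native, "chain"), inherits(config, "folding_config"))
  native_map <- compute_contact_map(native, config$cutoff)
  gamma_native <- connectivity_matrix(native_map, config$spring_constant)  # connectivity check
  init <- make_initial_chain(native, config)
  x <- init$coords - native$coords

  init_map <- compute_contact_map(init, config$cutoff)
  gamma <- connectivity_matrix(init_map, config$spring_constant)

  times <- 0
  states <- list(x)
  contact_maps <- list()
  gains <- list()
  cycle_start <- numeric(0)
  clashes <- list()
  converged <- FALSE
  cycles <- 0L
  t_now <- 0

  for (cycle in seq_len(config$max_cycles)) {
    current <- chain(native$coords + x, label = native$label)
    cmap <- compute_contact_map(current, config$cutoff)
    rmsd <- sqrt(mean(rowSums(x^2)))
    if (contact_maps_equal(cmap, native_map) && rmsd <= config$rmsd_tol) {
      converged <- TRUE
      break
    }
    cycles <- cycle
    cycle_start <- c(cycle_start, t_now)
    contact_maps[[cycle]] <- cmap
    if (config$update_gamma)
      gamma <- connectivity_matrix(cmap, config$spring_constant)

    Q <- build_Q(cmap, config$epsilon)
    prob <- lqr_problem(gamma, Q, alpha = config$alpha, beta = config$beta,
                        epsilon = config$epsilon)
    gain <- solve_lqr(prob)
    gains[[cycle]] <- gain
    A_cl <- closed_loop_matrix(gamma, gain, config$beta)

    seg <- simulate_segment(A_cl, x, config$t_sample, config$dt_record)
    times <- c(times, t_now + seg$times)
    states <- c(states, seg$states)
    x <- seg$states[[length(seg$states)]]
    t_now <- t_now + config$t_sample

    cl <- clash_pairs(native$coords + x, config$clash_dist)
    if (nrow(cl)) {
      clashes[[length(clashes) + 1L]] <- cbind(cycle = cycle, cl)
      message(sprintf("cycle %d: %d excluded-volume violation(s) (< %.1f A), closest %.2f A",
                      cycle, nrow(cl), config$clash_dist, min(cl[, "distance"])))
    }
  }

  if (!converged) {
    current <- chain(native$coords + x, label = native$label)
    cmap <- compute_contact_map(current, config$cutoff)
    rmsd <- sqrt(mean(rowSums(x^2)))
    if (contact_maps_equal(cmap, native_map) && rmsd <= config$rmsd_tol)
      converged <- TRUE
    else
      warning(sprintf(
        "did not converge in %d cycles (RMSD %.3f A, %d/%d native contacts)",
        config$max_cycles, rmsd, sum(interaction_count(cmap, native_map)),
        nrow(native_map$pairs)))
  }

  structure(
    list(times = times, states = states, contact_maps = contact_maps,
         gains = gains, cycle_start = cycle_start, converged = converged,
         cycles_used = cycles,
         clashes = if (length(clashes)) do.call(rbind, clashes)
                   else matrix(numeric(0), 0L, 4L,
                               dimnames = list(NULL, c("cycle", "i", "j", "distance"))),
         native = native, initial = init, config = config),
    class = "folding_trajectory")
}

# shared native contacts between a map and the native map
interaction_count <- function(cmap, native_map) {
  key <- function(p) paste(p[, 1L], p[, 2L])
  key(native_map$pairs) %in% key(cmap$pairs)
}

clash_pairs <- function(coords, clash_dist) {
  d <- as.matrix(stats::dist(coords))
  sep <- abs(row(d) - col(d))
  hit <- which(upper.tri(d) & sep > 1L & d < clash_dist, arr.ind = TRUE)
  cbind(i = hit[, 1L], j = hit[, 2L],
        distance = if (nrow(hit)) d[hit] else numeric(0))
}

#' @export
print.folding_trajectory <- function(x, ...) {
  cat(sprintf("<folding_trajectory> %s: %d residues, %d cycle(s), t = [0, %g], %s\n",
              x$native$label, x$native$n, x$cycles_used,
              max(x$times), if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Conformation at a recorded time index
#' @param traj a `folding_trajectory`.
#' @param index position in `traj$times`.
#' @return a [chain()] with `R = R_native + x`.
#' @export
conformation_at <- function(traj, index) {
  stopifnot(inherits(traj, "folding_trajectory"))
  if (index < 1L || index > length(traj$times)) stop("index out of range")
  chain(traj$native$coords + traj$states[[index]],
        label = sprintf("%s@t=%g", traj$native$label, traj$times[index]),
        pdb_resno = traj$native$pdb_resno, resid = traj$native$resid)
}

#' Export a trajectory as a tidy CSV table
#'
#' One row per recorded time per residue: deviations and absolute coordinates.
#'
#' @param traj a `folding_trajectory`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "folding_trajectory"))
  n <- traj$native$n
  rows <- lapply(seq_along(traj$times), function(ti) {
    x <- traj$states[[ti]]
    data.frame(time = traj$times[ti], residue = seq_len(n),
               dx = x[, 1L], dy = x[, 2L], dz = x[, 3L],
               x = traj$native$coords[, 1L] + x[, 1L],
               y = traj$native$coords[, 2L] + x[, 2L],
               z = traj$native$coords[, 3L] + x[, 3L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
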