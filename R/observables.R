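# Folding observables: fractional cluster contacts f(t), contact
# initiation/completion events, radius of gyration, pair distances, the
# energy / entropic-penalty decay, and (effective) contact order.

#' Define a cluster as a rectangle on the contact map
#'
#' Clusters (secondary-structure elements, turns, tertiary pairings) are
#' given as residue-range rectangles `i_range x j_range`; the native pairs
#' inside the rectangle are derived from the native contact map. Residue
#' ranges are user input: cluster identity depends on the fold and is not
#' hard-coded.
#'
#' @param name cluster label (e.g. `"T2"`, `"H1"`, `"b1-4"`).
#' @param i_range,j_range integer ranges of residue indices; a pair (i, j),
#'   i < j, belongs to the region if one index falls in `i_range` and the
#'   other in `j_range` (orientation-free).
#' @param native_map the native `contact_map`.
#' @param include_covalent count covalent (|i-j| = 1) pairs in the region;
#'   default `FALSE` (they carry no folding information).
#' @return an object of class `cluster_definition` with derived `native_pairs`.
#' @export
cluster_definition <- function(name, i_range, j_range, native_map,
                               include_covalent = FALSE) {
  stopifnot(inherits(native_map, "contact_map"))
  i_range <- as.integer(i_range); j_range <- as.integer(j_range)
  if (length(i_range) == 0L || length(j_range) == 0L)
    stop("empty cluster: residue ranges must be non-empty")
  if (min(i_range, j_range) < 1L || max(i_range, j_range) > native_map$n)
    stop("cluster region outside [1, n]")
  p <- native_map$pairs
  inr <- in_region(p, i_range, j_range)
  if (!include_covalent) inr <- inr & (p[, 2L] - p[, 1L] > 1L)
  native_pairs <- p[inr, , drop = FALSE]
  if (nrow(native_pairs) == 0L)
    stop("empty cluster: no native contacts in region '", name, "'")
  structure(
    list(name = name, i_range = i_range, j_range = j_range,
         native_pairs = native_pairs, include_covalent = include_covalent),
    class = "cluster_definition")
}

in_region <- function(pairs, i_range, j_range) {
  (pairs[, 1L] %in% i_range & pairs[, 2L] %in% j_range) |
  (pairs[, 2L] %in% i_range & pairs[, 1L] %in% j_range)
}

#' Read cluster definitions from a config file
#'
#' Plain whitespace/tab-separated table with header
#' `name i_start i_end j_start j_end`.
#'
#' @param path config file path.
#' @param native_map the native `contact_map`.
#' @return named list of [cluster_definition()] objects.
#' @export
read_cluster_config <- function(path, native_map) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "i_start", "i_end", "j_start", "j_end")
  if (!all(need %in% names(df)))
    stop("cluster config must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(r)
    cluster_definition(df$name[r], df$i_start[r]:df$i_end[r],
                       df$j_start[r]:df$j_end[r], native_map))
  names(out) <- df$name
  out
}

# all candidate pairs inside a cluster region (any pair, native or not)
region_pairs <- function(cluster, n) {
  idx <- expand.grid(i = cluster$i_range, j = cluster$j_range)
  i <- pmin(idx$i, idx$j); j <- pmax(idx$i, idx$j)
  keep <- i < j
  if (!cluster$include_covalent) keep <- keep & (j - i > 1L)
  unique(cbind(i = i[keep], j = j[keep]))
}

# m x T matrix of pair distances across all recorded times
pair_distance_matrix <- function(traj, pairs) {
  nat <- traj$native$coords
  vapply(seq_along(traj$times), function(ti) {
    co <- nat + traj$states[[ti]]
    sqrt(rowSums((co[pairs[, 1L], , drop = FALSE] -
                  co[pairs[, 2L], , drop = FALSE])^2))
  }, numeric(nrow(pairs)))
}

#' Fractional cluster contacts f(t)
#'
#' The number of pairs inside the cluster's rectangle formed (distance at or
#' below the cutoff) at each recorded time, divided by the number of native
#' pairs in the rectangle. Non-native pairs in the region are counted, so f
#' can exceed 1 while non-native contacts are present; pass
#' `native_only = TRUE` to count native pairs only (then f <= 1).
#'
#' @param traj a `folding_trajectory`.
#' @param cluster a [cluster_definition()].
#' @param native_only count only native pairs (default `FALSE`).
#' @return data.frame with columns `time`, `f`.
#' @export
fraction_contacts <- function(traj, cluster, native_only = FALSE) {
  stopifnot(inherits(traj, "folding_trajectory"),
            inherits(cluster, "cluster_definition"))
  pairs <- if (native_only) cluster$native_pairs
           else region_pairs(cluster, traj$native$n)
  D <- pair_distance_matrix(traj, pairs)
  D <- matrix(D, nrow = nrow(pairs))
  data.frame(time = traj$times,
             f = colSums(D <= traj$config$cutoff) / nrow(cluster$native_pairs))
}

#' Contact initiation and completion events
#'
#' One event per residue pair that is ever formed along the trajectory:
#' `t_init` is the first recorded time with distance at or below the cutoff,
#' `t_complete` the first recorded time after which the contact persists to
#' the end of the run. Times are resolved on the recording grid (no
#' interpolation). Events are sorted by `t_init`, then (i, j).
#'
#' @param traj a `folding_trajectory`.
#' @param cutoff contact cutoff; defaults to the run's cutoff.
#' @param include_covalent include |i-j| = 1 pairs (default `FALSE`).
#' @return data.frame with columns `i`, `j`, `co` (|i-j|), `t_init`,
#'   `t_complete`, `is_native`.
#' @export
contact_events <- function(traj, cutoff = NULL,
                           include_covalent = FALSE) {
  stopifnot(inherits(traj, "folding_trajectory"))
  if (length(traj$times) < 2L) stop("trajectory has fewer than 2 recorded times")
  if (is.null(cutoff)) cutoff <- traj$config$cutoff
  n <- traj$native$n
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- cbind(i = idx[, 1L], j = idx[, 2L])
  if (!include_covalent)
    pairs <- pairs[pairs[, 2L] - pairs[, 1L] > 1L, , drop = FALSE]
  D <- pair_distance_matrix(traj, pairs)
  formed <- D <= cutoff
  ever <- rowSums(formed) > 0L
  pairs <- pairs[ever, , drop = FALSE]
  formed <- formed[ever, , drop = FALSE]
  native_map <- compute_contact_map(traj$native, cutoff)
  nat_key <- paste(native_map$pairs[, 1L], native_map$pairs[, 2L])
  t_init <- traj$times[apply(formed, 1L, which.max)]
  tt <- c(traj$times, NA_real_)  # NA: broken at the end of the run
  t_complete <- tt[apply(formed, 1L, function(row) {
    off <- which(!row)
    if (length(off) == 0L) 1L else max(off) + 1L
  })]
  ev <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                   co = pairs[, 2L] - pairs[, 1L],
                   t_init = t_init, t_complete = t_complete,
                   is_native = paste(pairs[, 1L], pairs[, 2L]) %in% nat_key)
  ev <- ev[order(ev$t_init, ev$i, ev$j), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Radius of gyration
#'
#' `Rg = sqrt(mean(|r_i - centroid|^2))`: rotation/translation invariant and
#' linear under coordinate dilation.
#'
#' @param chain a [chain()] or an n x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(chain) {
  co <- if (inherits(chain, "chain")) chain$coords else as.matrix(chain)
  sqrt(mean(rowSums(sweep(co, 2L, colMeans(co))^2)))
}

#' Radius of gyration along a trajectory
#' @param traj a `folding_trajectory`.
#' @return data.frame with columns `time`, `rg`.
#' @export
rg_series <- function(traj) {
  stopifnot(inherits(traj, "folding_trajectory"))
  data.frame(time = traj$times,
             rg = vapply(traj$states, function(x)
               radius_of_gyration(traj$native$coords + x), numeric(1)))
}

#' Distance between two residues along a trajectory
#' @param traj a `folding_trajectory`.
#' @param i,j residue indices (internal 1..n numbering).
#' @return data.frame with columns `time`, `distance`.
#' @export
pair_distance_series <- function(traj, i, j) {
  stopifnot(inherits(traj, "folding_trajectory"))
  n <- traj$native$n
  if (i < 1L || j < 1L || i > n || j > n || i == j)
    stop("residue indices out of range or equal")
  p <- cbind(min(i, j), max(i, j))
  data.frame(time = traj$times,
             distance = as.numeric(pair_distance_matrix(traj, p)))
}

#' Instantaneous energy and entropic-penalty terms along a trajectory
#'
#' The two integrands of the realized LQR objective, `t(x) Q x` and
#' `alpha * t(u) P u` with `u = -K x`, evaluated on the recording grid with
#' the Q and gain of the cycle each time point belongs to, summed over the
#' three Cartesian axes. Both decay to ~0 on a converged run.
#'
#' @param traj a `folding_trajectory`.
#' @return data.frame with columns `time`, `state_term`, `control_term`,
#'   `cycle`.
#' @export
cost_decay_series <- function(traj) {
  stopifnot(inherits(traj, "folding_trajectory"))
  if (length(traj$gains) == 0L)
    return(data.frame(time = traj$times, state_term = 0, control_term = 0,
                      cycle = 0L))
  cyc <- pmin(pmax(findInterval(traj$times, traj$cycle_start,
                                left.open = TRUE) + 1L, 1L),
              length(traj$gains))
  alpha <- traj$config$alpha
  out <- vapply(seq_along(traj$times), function(ti) {
    g <- traj$gains[[cyc[ti]]]
    x <- traj$states[[ti]]
    u <- -g$K %*% x
    c(sum(x * (g$Q %*% x)), alpha * sum(u * (g$P %*% u)))
  }, numeric(2))
  data.frame(time = traj$times, state_term = out[1L, ],
             control_term = out[2L, ], cycle = cyc)
}

#' Effective contact order (ECO)
#'
#' Shortest path between residues i and j in the graph whose edges are the
#' covalent bonds plus every already-formed contact, each of weight 1: a
#' proxy for the entropic cost of closing the i-j loop. With no formed
#' contacts this is the plain contact order |i - j|; adding contacts never
#' increases it.
#'
#' @param i,j residue indices, i != j.
#' @param formed set of formed pairs: m x 2 matrix, a `contact_map`, or
#'   `NULL` for none.
#' @param n chain length.
#' @return integer path length.
#' @export
effective_contact_order <- function(i, j, formed = NULL, n) {
  if (inherits(formed, "contact_map")) {
    n <- formed$n
    formed <- formed$pairs
  }
  if (i < 1L || j < 1L || i > n || j > n || i == j)
    stop("residue indices out of range or equal")
  edges <- cbind(seq_len(n - 1L), 2L:n)
  if (NROW(formed)) edges <- rbind(edges, as.matrix(formed)[, 1:2, drop = FALSE])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  as.integer(igraph::distances(g, v = i, to = j))
}

#' Write contact events to CSV
#' @param events data.frame from [contact_events()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_contact_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
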