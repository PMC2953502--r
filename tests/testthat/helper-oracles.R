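# Independent oracles and small random-instance generators used across the
# suite. These deliberately avoid the package's own construction paths.

# Brute-force Q - eps*I: sum over non-covalent contact pairs of t(D_ij) D_ij,
# D_ij the row vector with -1 at i and +1 at j.
brute_force_Q <- function(pairs, n, epsilon) {
  Q <- matrix(0, n, n)
  for (r in seq_len(NROW(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (j - i == 1L) next
    D <- rep(0, n); D[i] <- -1; D[j] <- 1
    Q <- Q + outer(D, D)
  }
  Q + epsilon * diag(n)
}

# Exhaustive shortest path by breadth-less enumeration of simple paths.
exhaustive_shortest_path <- function(i, j, edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(NROW(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  best <- Inf
  walk <- function(node, visited, len) {
    if (len >= best) return()
    if (node == j) { best <<- len; return() }
    for (nb in adj[[node]]) if (!visited[nb]) {
      visited[nb] <- TRUE
      walk(nb, visited, len + 1L)
      visited[nb] <- FALSE
    }
  }
  v <- rep(FALSE, n); v[i] <- TRUE
  walk(i, v, 0L)
  best
}

# Random geometric chain: consecutive beads 3.8 A apart, mild random turns,
# so the contact graph is always connected through the backbone.
random_chain <- function(n) {
  coords <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    turn <- stats::rnorm(3, sd = 0.6)
    dir <- dir + turn
    dir <- dir / sqrt(sum(dir^2))
    coords[i, ] <- coords[i - 1, ] + 3.8 * dir
  }
  chain(coords, label = sprintf("random%d", n))
}

# Random contact map over n residues: the covalent path plus random
# non-covalent pairs (a synthetic pair-set, not derived from geometry).
random_contact_map <- function(n, p = 0.2) {
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cov <- all_pairs[, 2] - all_pairs[, 1] == 1L
  keep <- cov | stats::runif(nrow(all_pairs)) < p
  pairs <- all_pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(n = n,
                 pairs = cbind(i = as.integer(pairs[, 1]),
                               j = as.integer(pairs[, 2])),
                 dist = rep(5, nrow(pairs)), cutoff = 7),
            class = "contact_map")
}

hairpin_native <- function() make_fixture("helix_hairpin", 20)

quiet_run <- function(...) suppressMessages(run_folding(...))
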