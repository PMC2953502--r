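# Contact maps, graph Laplacians, the LQR state weight Q and the
# Gaussian-network connectivity matrix Gamma.

#' Compute the contact map of a conformation
#'
#' A contact is any residue pair whose C-alpha separation is at or below the
#' cutoff. The map is a pure geometric object: covalent neighbours are
#' included when within the cutoff and are removed later, algebraically,
#' where the model requires it (see [build_Q()]).
#'
#' @param chain a [chain()] object.
#' @param cutoff contact distance cutoff in Angstrom (default 7).
#' @return an object of class `contact_map` with fields `n`, `pairs`
#'   (m x 2 integer matrix, i < j), `dist` (Angstrom per pair), `cutoff`.
#' @export
compute_contact_map <- function(chain, cutoff = 7) {
  stopifnot(inherits(chain, "chain"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive scalar")
  d <- as.matrix(stats::dist(chain$coords))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  ord <- order(hit[, 1L], hit[, 2L])
  pairs <- cbind(i = as.integer(hit[ord, 1L]), j = as.integer(hit[ord, 2L]))
  structure(
    list(n = chain$n, pairs = pairs, dist = d[hit][ord], cutoff = cutoff),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  co <- if (nrow(x$pairs)) x$pairs[, 2L] - x$pairs[, 1L] else integer(0)
  cat(sprintf("<contact_map> n = %d, cutoff = %g A, %d pairs (%d non-covalent)\n",
              x$n, x$cutoff, nrow(x$pairs), sum(co > 1L)))
  invisible(x)
}

#' @export
as.matrix.contact_map <- function(x, ...) {
  C <- matrix(0L, x$n, x$n)
  if (nrow(x$pairs)) {
    C[x$pairs] <- 1L
    C[x$pairs[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  C
}

#' Test two contact maps for set equality
#' @param a,b `contact_map` objects over the same number of residues.
#' @return `TRUE` if both maps contain exactly the same pairs.
#' @export
contact_maps_equal <- function(a, b) {
  stopifnot(inherits(a, "contact_map"), inherits(b, "contact_map"))
  a$n == b$n && nrow(a$pairs) == nrow(b$pairs) && all(a$pairs == b$pairs)
}

# Laplacian of an arbitrary pair list over n nodes.
laplacian_of_pairs <- function(pairs, n) {
  L <- matrix(0, n, n)
  if (NROW(pairs)) {
    pairs <- as.matrix(pairs)
    L[pairs] <- L[pairs] - 1
    L[pairs[, c(2L, 1L), drop = FALSE]] <- L[pairs[, c(2L, 1L), drop = FALSE]] - 1
    diag(L) <- -rowSums(L)
  }
  L
}

#' Graph Laplacian of a contact map
#'
#' Off-diagonal entries are -1 for contacting pairs and 0 otherwise; the
#' diagonal holds node degrees, so all row sums vanish and the spectrum has
#' exactly one zero eigenvalue for a connected graph, the rest positive.
#'
#' @param cmap a `contact_map`.
#' @return n x n symmetric Laplacian matrix.
#' @export
laplacian_from_contacts <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  laplacian_of_pairs(cmap$pairs, cmap$n)
}

# Laplacian of the covalent path graph 1-2-...-n restricted to pairs that
# are present in the map. In practice every virtual bond (~3.8 A) sits well
# inside any sensible cutoff, in which case this is the full path graph.
covalent_laplacian <- function(cmap) {
  cov <- cmap$pairs[cmap$pairs[, 2L] - cmap$pairs[, 1L] == 1L, , drop = FALSE]
  laplacian_of_pairs(cov, cmap$n)
}

#' Build the LQR state weight Q from a contact map
#'
#' Q is the contact Laplacian with the covalent-bond Laplacian removed, plus
#' a small ridge: `Q = L - L_bb + epsilon * I`. The difference `L - L_bb`
#' is exactly the sum over non-covalent contact pairs (i, j) of
#' `t(D_ij) %*% D_ij`, where `D_ij` is the row vector with -1 at i and +1
#' at j, i.e. the quadratic form measuring squared pair-distance deviations
#' from the native values. The ridge makes Q positive definite, which the
#' regulator needs to stabilize the zero (translational) mode; all row sums
#' of Q equal `epsilon`.
#'
#' @param cmap a `contact_map`.
#' @param epsilon positive ridge; small values mean weak anchoring of each
#'   residue to its native position (default 0.01).
#' @return n x n symmetric positive-definite matrix.
#' @export
build_Q <- function(cmap, epsilon = 0.01) {
  stopifnot(inherits(cmap, "contact_map"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("Q would not be positive definite: epsilon must be > 0")
  L <- laplacian_from_contacts(cmap)
  Q <- L - covalent_laplacian(cmap)
  diag(Q) <- diag(Q) + epsilon
  Q
}

#' Gaussian-network connectivity matrix Gamma
#'
#' The negative-semidefinite spring matrix of the Gaussian network built on
#' the contact graph plus the covalent backbone path (the backbone is always
#' included so the network is never disconnected by a stretched bond):
#' `Gamma = -spring_constant * L`. For a connected chain Gamma has exactly
#' one zero eigenvalue (rigid translation) and n-1 negative ones.
#'
#' @param cmap a `contact_map`.
#' @param spring_constant uniform spring constant (default 1; the model's
#'   time unit absorbs it together with the friction coefficient).
#' @return n x n symmetric negative-semidefinite matrix.
#' @export
connectivity_matrix <- function(cmap, spring_constant = 1) {
  stopifnot(inherits(cmap, "contact_map"))
  if (!is.numeric(spring_constant) || length(spring_constant) != 1L ||
      spring_constant <= 0)
    stop("spring_constant must be a positive scalar")
  n <- cmap$n
  cov <- cbind(seq_len(n - 1L), 2L:n)
  pairs <- unique(rbind(cmap$pairs, cov))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (igraph::vcount(g) < n || !igraph::is_connected(g))
    stop("connectivity matrix has >1 zero eigenvalue: contact graph is disconnected")
  -spring_constant * laplacian_of_pairs(pairs, n)
}

#' Write a contact map to a text file
#'
#' Either a 3-column pair list (`i j distance`, 1-based indices) or a dense
#' 0/1 matrix in CSV form.
#'
#' @param cmap a `contact_map`.
#' @param path output file path.
#' @param format `"pairs"` (default) or `"matrix"`.
#' @return invisibly, `path`.
#' @export
write_contact_map <- function(cmap, path, format = c("pairs", "matrix")) {
  stopifnot(inherits(cmap, "contact_map"))
  format <- match.arg(format)
  if (format == "pairs") {
    df <- data.frame(i = cmap$pairs[, 1L], j = cmap$pairs[, 2L],
                     distance = round(cmap$dist, 4))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(as.matrix(cmap), path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a pair-list contact map written by [write_contact_map()]
#' @param path pair-list file path.
#' @param n residue count of the underlying chain.
#' @param cutoff the cutoff recorded with the map.
#' @return a `contact_map`.
#' @export
read_contact_map <- function(path, n, cutoff = 7) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(
    list(n = as.integer(n),
         pairs = cbind(i = as.integer(df$i), j = as.integer(df$j)),
         dist = as.numeric(df$distance), cutoff = cutoff),
    class = "contact_map")
}
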