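# Synthetic native structures: ideal helix, helix-hairpin, extended chain,
# two-domain. These stand in for experimental folds so the whole pipeline is
# testable offline; they are labelled synthetic and carry canonical
# alpha-helix C-alpha geometry (rise 1.5 A, radius 2.3 A, 100 deg/residue;
# virtual bond 3.8 A), giving consecutive C-alpha distances in [3.7, 3.9] A.

helix_points <- function(n, phase = 0, z0 = 0, descending = FALSE,
                         center = c(0, 0)) {
  i <- 0:(n - 1L)
  th <- phase + (100 * pi / 180) * i
  z <- if (descending) z0 - 1.5 * i else z0 + 1.5 * i
  cbind(center[1L] + 2.3 * cos(th), center[2L] + 2.3 * sin(th), z)
}

extended_points <- function(n, bond = 3.8) {
  cbind(bond * (seq_len(n) - 1L), 0, 0)
}

# Place `n_turn` bridge residues between two fixed anchors so that all
# bridging virtual bonds are 3.8 A and no bead clashes (< 3.9 A non-bonded).
# Deterministic: quasi-Newton refinement from a fixed arc-shaped start.
place_turn <- function(before, after, p_prev, p_next, n_turn = 4L) {
  k <- seq_len(n_turn)
  init <- t(sapply(k, function(m) p_prev + (m / (n_turn + 1)) * (p_next - p_prev)))
  init[, 2L] <- init[, 2L] + c(2.5, 4, 4, 2.5)[seq_len(n_turn)]  # bulge out
  obj <- function(v) {
    turn <- matrix(v, n_turn, 3L)
    ch <- rbind(before, turn, after)
    nb <- nrow(before)
    bonds <- sqrt(rowSums((ch[-1L, , drop = FALSE] - ch[-nrow(ch), , drop = FALSE])^2))
    jb <- bonds[nb:(nb + n_turn)]      # the bonds touching the turn
    d <- as.matrix(stats::dist(ch))
    nonbond <- d[abs(row(d) - col(d)) > 1L & upper.tri(d)]
    100 * sum((jb - 3.8)^2) + 10 * sum(pmax(0, 3.9 - nonbond)^2)
  }
  o <- stats::optim(as.numeric(init), obj, method = "BFGS",
                    control = list(maxit = 500L, reltol = 1e-14))
  if (o$value > 1e-6)
    stop("turn placement failed to satisfy bond-length constraints")
  matrix(o$par, n_turn, 3L)
}

#' Generate a synthetic native structure
#'
#' Kinds:
#' * `ideal_helix` — one canonical alpha helix; every (i, i+3) and (i, i+4)
#'   pair is a native contact at a 7 A cutoff.
#' * `extended` — straight chain with 3.8 A virtual bonds; no non-covalent
#'   contacts at 7 A (2 x 3.8 > 7).
#' * `helix_hairpin` — two helices of `(n - 4) / 2` residues joined by a
#'   4-residue turn and packed antiparallel (axis separation 8 A), giving
#'   both local (helical) and non-local (inter-helix) native contacts.
#' * `two_domain` — two helical contact-dense blocks joined by an extended
#'   linker of 6 residues, giving a sparse inter-domain region.
#'
#' Generation is deterministic given `kind` and `n`.
#'
#' @param kind fixture kind.
#' @param n residue count (helix_hairpin needs n >= 16 with `n - 4` even;
#'   two_domain needs n >= 22).
#' @return a [chain()] labelled `synthetic:<kind><n>`.
#' @export
make_fixture <- function(kind = c("ideal_helix", "helix_hairpin",
                                  "extended", "two_domain"), n = 20L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  coords <- switch(kind,
    ideal_helix = {
      if (n < 3L) stop("ideal_helix needs n >= 3")
      helix_points(n)
    },
    extended = {
      if (n < 3L) stop("extended needs n >= 3")
      extended_points(n)
    },
    helix_hairpin = {
      if (n < 16L || (n - 4L) %% 2L != 0L)
        stop("helix_hairpin needs n >= 16 with n - 4 even")
      h <- (n - 4L) %/% 2L
      A <- helix_points(h)                                  # ascending
      ztop <- 1.5 * (h - 1L) + 2
      B <- helix_points(h, phase = pi, z0 = ztop, descending = TRUE,
                        center = c(8, 0))
      turn <- place_turn(A, B, A[h, ], B[1L, ])
      rbind(A, turn, B)
    },
    two_domain = {
      if (n < 22L) stop("two_domain needs n >= 22")
      n_link <- 6L
      h1 <- (n - n_link) %/% 2L
      h2 <- n - n_link - h1
      A <- helix_points(h1)
      # extended linker marching away from domain A along +x
      start <- A[h1, ]
      link <- t(sapply(seq_len(n_link), function(k) start + c(3.8 * k, 0, 0)))
      b0 <- link[n_link, ] + c(3.8, 0, 0)
      # phase pi starts the second helix winding away from the linker line
      B <- helix_points(h2, phase = pi, z0 = b0[3L], center = b0[1:2])
      B <- sweep(B, 2L, B[1L, ] - b0)  # first residue sits on the 3.8 A bond
      rbind(A, link, B)
    })
  chain(coords, label = sprintf("synthetic:%s%d", kind, n))
}
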