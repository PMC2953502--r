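# Infinite-horizon LQR synthesis for the folding network: algebraic Riccati
# solution, gain decomposition into harmonic springs + native anchor, and
# closed-loop cost integrals.

#' Assemble an LQR problem for the folding network
#'
#' The overdamped per-axis dynamics are `beta * dx/dt = Gamma x + u`, i.e.
#' `dx/dt = A x + B u` with `A = Gamma / beta` and `B = I / beta`. The
#' regulator minimizes `integral( t(x) Q x + alpha * t(u) P u ) dt`; `alpha`
#' trades energy descent against the entropic penalty on large forces, and
#' `P` defaults to the identity (every force component weighted equally).
#'
#' @param gamma n x n connectivity matrix from [connectivity_matrix()].
#' @param Q n x n symmetric positive-definite state weight from [build_Q()].
#' @param alpha positive trade-off scalar; larger alpha penalizes control
#'   effort (entropy loss) more and slows folding.
#' @param beta friction coefficient (force * time / length); sets the time
#'   unit, default 1.
#' @param P control weight, symmetric positive definite; default identity.
#' @param epsilon the ridge used to build `Q` (needed for the analytic
#'   anchor constant of the gain decomposition).
#' @return an object of class `lqr_problem`.
#' @export
lqr_problem <- function(gamma, Q, alpha = 1, beta = 1, P = NULL, epsilon = 0.01) {
  gamma <- as.matrix(gamma); Q <- as.matrix(Q)
  n <- nrow(gamma)
  stopifnot(ncol(gamma) == n, all(dim(Q) == n))
  if (alpha <= 0) stop("alpha must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  p_identity <- is.null(P)
  if (p_identity) P <- diag(n) else P <- as.matrix(P)
  stopifnot(all(dim(P) == n))
  structure(
    list(A = gamma / beta, B = diag(n) / beta, gamma = gamma, Q = Q, P = P,
         alpha = alpha, beta = beta, epsilon = epsilon, n = n,
         p_identity = p_identity),
    class = "lqr_problem")
}

# Solve t(Acl) X + X Acl + M = 0 for stable Acl.
# Symmetric Acl: spectral decomposition gives the solution exactly.
# Non-symmetric (general P): complex eigendecomposition, generically valid.
solve_lyapunov <- function(Acl, M) {
  n <- nrow(Acl)
  if (isSymmetric(Acl, tol = 1e-10)) {
    e <- eigen((Acl + t(Acl)) / 2, symmetric = TRUE)
    if (max(e$values) >= 0) stop("Lyapunov solve requires a stable matrix")
    Mt <- crossprod(e$vectors, M %*% e$vectors)
    X <- Mt / -outer(e$values, e$values, "+")
    e$vectors %*% X %*% t(e$vectors)
  } else {
    e <- eigen(Acl)
    if (max(Re(e$values)) >= 0) stop("Lyapunov solve requires a stable matrix")
    Vi <- solve(e$vectors)
    Mt <- t(e$vectors) %*% M %*% e$vectors
    X <- Mt / -outer(e$values, e$values, "+")
    Re(t(Vi) %*% X %*% Vi)
  }
}

# Continuous algebraic Riccati equation t(A) S + S A - S G S + Q = 0,
# G = B solve(R) t(B) positive definite, by Newton-Kleinman iteration with
# exact Lyapunov solves. S0 = I is stabilizing here because A is negative
# semidefinite and G is positive definite, so A - G is negative definite.
solve_care <- function(A, G, Q, tol = 1e-12, maxit = 60L) {
  n <- nrow(A)
  S <- diag(n)
  for (it in seq_len(maxit)) {
    Acl <- A - G %*% S
    S_new <- solve_lyapunov(Acl, S %*% G %*% S + Q)
    S_new <- (S_new + t(S_new)) / 2
    delta <- max(abs(S_new - S)) / max(1, max(abs(S_new)))
    S <- S_new
    if (delta < tol) break
  }
  S
}

riccati_residual <- function(S, A, G, Q) {
  max(abs(t(A) %*% S + S %*% A - S %*% G %*% S + Q))
}

#' Solve the LQR problem and decompose the optimal gain
#'
#' Solves the continuous algebraic Riccati equation
#' `t(A) S + S A - S B solve(alpha P) t(B) S + Q = 0` for the stabilizing
#' `S > 0` and returns the feedback law `u = -K x` with
#' `K = solve(alpha P) t(B) S`. The gain splits as `K = K_prime + k * I`:
#' `K_prime` is the synthesized harmonic spring-constant matrix (all row
#' sums zero) and `k` anchors every residue to its native position with the
#' same spring. With `P = I`, `Gamma %*% 1 = 0` and `Q %*% 1 = epsilon * 1`,
#' the span of the all-ones vector is invariant under the Riccati map, which
#' gives the anchor in closed form: `k = sqrt(epsilon / alpha)`. The row-sum
#' identity is re-checked numerically on every solve, making the
#' decomposition exact rather than a fit.
#'
#' @param problem an [lqr_problem()].
#' @return an object of class `gain_decomposition` with fields `K`,
#'   `K_prime`, `k`, `S` (Riccati solution), `residual` (max-abs Riccati
#'   residual) and the problem parameters.
#' @export
solve_lqr <- function(problem) {
  stopifnot(inherits(problem, "lqr_problem"))
  A <- problem$A; B <- problem$B
  R <- problem$alpha * problem$P
  G <- B %*% solve(R, t(B))
  G <- (G + t(G)) / 2
  S <- tryCatch(solve_care(A, G, problem$Q),
                error = function(e) stop("no stabilizing solution: ",
                                         conditionMessage(e)))
  res <- riccati_residual(S, A, G, problem$Q)
  nq <- norm(problem$Q, "F")
  if (!is.finite(res) || res > 1e-8 * nq)
    stop(sprintf("no stabilizing solution: Riccati residual %.3g exceeds 1e-8 * ||Q||", res))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("no stabilizing solution: Riccati solution not positive definite")

  K <- solve(R, t(B) %*% S)
  if (problem$p_identity) K <- (K + t(K)) / 2
  k <- sqrt(problem$epsilon / problem$alpha)
  K_prime <- K - k * diag(problem$n)
  # the row-sum identity follows from the all-ones invariant subspace; it
  # holds exactly when P = I, Gamma %*% 1 = 0 and Q %*% 1 = epsilon * 1
  ones_invariant <- problem$p_identity &&
    max(abs(problem$A %*% rep(1, problem$n))) < 1e-10 &&
    max(abs(problem$Q %*% rep(1, problem$n) - problem$epsilon)) < 1e-10
  if (ones_invariant) {
    dev <- max(abs(rowSums(K_prime)))
    if (dev > 1e-8 * max(1e-12, norm(K, "F")))
      stop(sprintf("gain decomposition failed: row-sum deviation %.3g", dev))
  }
  structure(
    list(K = K, K_prime = K_prime, k = k, S = S, residual = res,
         alpha = problem$alpha, beta = problem$beta, epsilon = problem$epsilon,
         P = problem$P, Q = problem$Q),
    class = "gain_decomposition")
}

#' @export
print.gain_decomposition <- function(x, ...) {
  cat(sprintf("<gain_decomposition> n = %d, anchor k = %.4g, Riccati residual = %.2e\n",
              nrow(x$K), x$k, x$residual))
  invisible(x)
}

#' Closed-loop Gaussian-network matrix
#'
#' Under the optimal control the per-axis dynamics become
#' `beta * dx/dt = (Gamma - K_prime - k I) x`: a Gaussian network whose
#' connectivity is the original springs plus the synthesized ones, anchored
#' to the native state. The result must be strictly stable (all eigenvalues
#' negative) for the native state to be attractive.
#'
#' @param gamma n x n connectivity matrix.
#' @param gain a `gain_decomposition` from [solve_lqr()].
#' @param beta friction coefficient.
#' @return n x n closed-loop matrix `(Gamma - K) / beta`.
#' @export
closed_loop_matrix <- function(gamma, gain, beta = 1) {
  stopifnot(inherits(gain, "gain_decomposition"))
  gamma <- as.matrix(gamma)
  if (!all(dim(gamma) == dim(gain$K))) stop("shapes disagree")
  A_cl <- (gamma - gain$K) / beta
  sym <- isSymmetric(A_cl, tol = 1e-9)
  ev <- if (sym) eigen((A_cl + t(A_cl)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values
        else Re(eigen(A_cl, only.values = TRUE)$values)
  if (max(ev) >= 0)
    stop(sprintf("closed loop unstable: max eigenvalue %.3g >= 0", max(ev)))
  A_cl
}

#' Infinite-horizon cost integrals along the closed loop
#'
#' Splits the realized LQR objective into its state (energy) term
#' `integral t(x) Q x dt` and control (entropic penalty) term
#' `integral alpha * t(u) P u dt` with `u = -K x` along
#' `x(t) = expm(A_cl t) x0`, evaluated in closed form through Lyapunov
#' equations `t(A_cl) X + X A_cl + M = 0`, cost `= t(x0) X x0`.
#'
#' @param A_cl stable closed-loop matrix.
#' @param K feedback gain (matrix or `gain_decomposition`).
#' @param Q,P the LQR weights.
#' @param alpha trade-off scalar.
#' @param x0 initial deviation: length-n vector or n x 3 matrix (axes are
#'   independent and their costs add).
#' @return list with `state_cost` and `control_cost` scalars.
#' @export
lqr_cost_integrals <- function(A_cl, K, Q, P = NULL, alpha = 1, x0) {
  if (inherits(K, "gain_decomposition")) K <- K$K
  A_cl <- as.matrix(A_cl); n <- nrow(A_cl)
  if (is.null(P)) P <- diag(n)
  x0 <- if (is.matrix(x0)) x0 else matrix(x0, ncol = 1L)
  X_state <- solve_lyapunov(A_cl, Q)
  X_ctrl <- solve_lyapunov(A_cl, alpha * t(K) %*% P %*% K)
  list(state_cost = sum(colSums(x0 * (X_state %*% x0))),
       control_cost = sum(colSums(x0 * (X_ctrl %*% x0))))
}
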