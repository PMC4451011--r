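# AR(1) kinematic prior: the smoothness model over intended cursor kinematics.
#
# The intention x_t (n-dimensional) evolves as x_t = P x_{t-1} + z_t with
# z_t ~ N(0, Q). Stationarity (spectral radius of P below one) gives a
# marginal covariance Sigma_x solving the discrete Lyapunov equation
# Sigma_x = P Sigma_x P' + Q.

#' Construct an AR(1) kinematic prior
#'
#' The prior over intended kinematics used by Kalman-filter cursor decoders:
#' a first-order autoregression `x_t = P x_{t-1} + z_t`, `z_t ~ N(0, Q)`.
#' `P` controls per-step persistence (for position-only control typically
#' `rho * I` with `rho` just under 1), `Q` the per-step process noise in
#' squared kinematic units.
#'
#' @param P n x n transition matrix, or a scalar/vector shorthand for a
#'   diagonal matrix when `n` is given. Spectral radius must be < 1.
#' @param Q n x n process-noise covariance (symmetric positive semidefinite),
#'   or scalar/vector shorthand.
#' @param n state dimension; inferred from `P` when omitted.
#' @return an object of class `kinematic_prior` with fields `P`, `Q`, `n`.
#' @examples
#' prior <- kinematic_prior(P = 0.99, Q = 0.01, n = 1)
#' solve_lyapunov(prior)$Sigma_x   # about 0.5025
#' @export
kinematic_prior <- function(P, Q, n = NULL) {
  if (is.null(n)) {
    if (is.null(dim(P))) n <- length(P) else n <- nrow(P)
  }
  P <- as_matrix(P, n, "P")
  Q <- as_matrix(Q, n, "Q")
  if (max(abs(Q - t(Q))) > 1e-12 * (1 + max(abs(Q))))
    stop("Q must be symmetric", call. = FALSE)
  Q <- sym(Q)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop("Q must be positive semidefinite", call. = FALSE)
  if (min(ev) < 0) { # clip tiny negative eigenvalues from roundoff
    e <- eigen(sym(Q), symmetric = TRUE)
    Q <- sym(e$vectors %*% (pmax(e$values, 0) * t(e$vectors)))
  }
  rho <- spectral_radius(P)
  if (rho >= 1)
    stop(sprintf("prior is non-stationary: spectral radius of P is %.6g >= 1", rho),
         call. = FALSE)
  structure(list(P = P, Q = Q, n = as.integer(n)), class = "kinematic_prior")
}

#' @export
print.kinematic_prior <- function(x, ...) {
  cat(sprintf("AR(1) kinematic prior: n = %d, spectral radius(P) = %.4f\n",
              x$n, spectral_radius(x$P)))
  invisible(x)
}

#' Stationary covariance of the kinematic prior
#'
#' Solves the discrete Lyapunov equation `Sigma_x = P Sigma_x P' + Q` in
#' closed form by vectorization. `Sigma_x` is the marginal covariance of the
#' intention process and enters both the encoder penalties and the
#' closed-loop error analysis.
#'
#' @param prior a [kinematic_prior()]
#' @return a list of class `stationary_covariance` with field `Sigma_x`.
#' @export
solve_lyapunov <- function(prior) {
  stopifnot(inherits(prior, "kinematic_prior"))
  Sigma_x <- dlyap(prior$P, prior$Q)
  structure(list(Sigma_x = Sigma_x), class = "stationary_covariance")
}

#' Sample an intention trajectory from the prior
#'
#' Draws `x_0 ~ N(0, Sigma_x)` (a stationary start) and iterates
#' `x_t = P x_{t-1} + z_t`.
#'
#' @param prior a [kinematic_prior()]
#' @param T_steps number of steps to return (>= 1)
#' @param seed optional integer seed for reproducibility
#' @param x0 optional fixed initial state (overrides the stationary draw)
#' @return a `T_steps` x n matrix of states
#' @export
sample_trajectory <- function(prior, T_steps, seed = NULL, x0 = NULL) {
  stopifnot(inherits(prior, "kinematic_prior"))
  if (T_steps < 1) stop("T_steps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- prior$n
  R_q <- chol_psd(prior$Q)   # Q = t(R_q) %*% R_q
  if (is.null(x0)) {
    Sigma_x <- solve_lyapunov(prior)$Sigma_x
    x0 <- drop(t(chol_psd(Sigma_x)) %*% stats::rnorm(n))
  }
  Z <- matrix(stats::rnorm(T_steps * n), T_steps, n) %*% R_q
  X <- matrix(0, T_steps, n)
  x <- as.numeric(x0)
  for (t in seq_len(T_steps)) {
    x <- drop(prior$P %*% x) + Z[t, ]
    X[t, ] <- x
  }
  X
}
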