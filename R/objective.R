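# Exact stationary evaluation of the mean-squared-error objective for an
# arbitrary (not necessarily optimal) encoder-decoder pair.
#
# The coupled (intention, decoded-cursor) process
#   x_t    = P x_{t-1} + z_t
#   xhat_t = F A P x_{t-1} + G xhat_{t-1} + F A z_t + F eps_t
# is a linear system in the augmented state s_t = (x_t, xhat_t), so its
# stationary second moments solve one 2n x 2n Lyapunov equation and the
# stationary MSE  E ||xhat_t - x_t||^2  is available in closed form.  This
# is what makes gradient-based encoder optimization cheap: no simulation is
# needed to evaluate the objective.

#' Augmented transition and noise matrices of the coupled process
#' @keywords internal
augmented_system <- function(A, F_gain, G, prior, C) {
  n <- prior$n
  FA <- F_gain %*% A
  M <- rbind(cbind(prior$P, matrix(0, n, n)),
             cbind(FA %*% prior$P, G))
  FAQ <- FA %*% prior$Q
  W <- rbind(cbind(prior$Q, t(FAQ)),
             cbind(FAQ, sym(FAQ %*% t(FA) + F_gain %*% C %*% t(F_gain))))
  list(M = M, W = sym(W))
}

#' Stationary joint moments of intention and decoded cursor
#'
#' Solves the augmented Lyapunov equation for the coupled
#' (intention, decoded-cursor) process and returns its blocks:
#' `Sxx = E[x x']` (equals the prior's stationary covariance),
#' `Sxh = E[x xhat']`, `Shh = E[xhat xhat']`, all contemporaneous at
#' stationarity. The lagged cross moment `E[x_t xhat_{t-1}'] = P Sxh` is
#' also returned (it appears in the expanded form of the error).
#'
#' @param A k x n encoding matrix
#' @param F_gain n x k decoder gain
#' @param G n x n decoder recursion matrix
#' @param prior a [kinematic_prior()]
#' @param C k x k channel noise covariance
#' @return list of class `joint_moments` with `Sxx`, `Sxh`, `Shh`,
#'   `Sxh_lagged`, and the augmented matrices `M`, `S`.
#' @export
stationary_joint_moments <- function(A, F_gain, G, prior, C) {
  stopifnot(inherits(prior, "kinematic_prior"))
  n <- prior$n
  A <- as.matrix(A); F_gain <- as.matrix(F_gain); G <- as_matrix(G, n, "G")
  sys <- augmented_system(A, F_gain, G, prior, C)
  rho <- spectral_radius(sys$M)
  if (rho >= 1)
    stop(sprintf("augmented system is unstable (spectral radius %.4f >= 1): divergent decoder", rho),
         call. = FALSE)
  S <- dlyap(sys$M, sys$W)
  ix <- seq_len(n); ih <- n + seq_len(n)
  Sxh <- S[ix, ih, drop = FALSE]
  structure(list(Sxx = S[ix, ix, drop = FALSE],
                 Sxh = Sxh,
                 Shh = S[ih, ih, drop = FALSE],
                 Sxh_lagged = prior$P %*% Sxh,
                 M = sys$M, S = S),
            class = "joint_moments")
}

#' Stationary mean-squared error of an encoder-decoder pair
#'
#' `E ||xhat_t - x_t||^2 = tr(Shh - 2 Sxh + Sxx)` evaluated exactly at
#' stationarity from the augmented Lyapunov solve.
#'
#' @inheritParams stationary_joint_moments
#' @return scalar MSE (squared kinematic units)
#' @export
mse_objective <- function(A, F_gain, G, prior, C) {
  m <- stationary_joint_moments(A, F_gain, G, prior, C)
  sum(diag(m$Shh)) - 2 * sum(diag(m$Sxh)) + sum(diag(m$Sxx))
}

#' Penalized full objective for an encoder-decoder pair
#'
#' `total = mse + lambda * penalty`, where the penalty is the
#' trace-of-quotient penalty ([penalty_joint()]) or the SNR penalty
#' ([penalty_snr()]) on the encoding matrix.
#'
#' @inheritParams stationary_joint_moments
#' @param lambda penalty weight (>= 0)
#' @param penalty_kind `"joint"` or `"snr"`
#' @param Sigma_y_ref optional fixed reference total covariance for the
#'   joint penalty (see [penalty_joint()])
#' @return list of class `objective_value` with `mse`, `penalty`, `total`,
#'   `lambda`
#' @export
full_objective <- function(A, F_gain, G, prior, C, lambda = 1,
                           penalty_kind = c("joint", "snr"),
                           Sigma_y_ref = NULL) {
  penalty_kind <- match.arg(penalty_kind)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  mse <- mse_objective(A, F_gain, G, prior, C)
  enc <- encoder(A, C)
  Sigma_x <- solve_lyapunov(prior)$Sigma_x
  pen <- switch(penalty_kind,
    joint = penalty_joint(enc, Sigma_x, Sigma_y_ref = Sigma_y_ref),
    snr   = penalty_snr(enc, Sigma_x))
  structure(list(mse = mse, penalty = pen, total = mse + lambda * pen,
                 lambda = lambda, penalty_kind = penalty_kind),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("objective: mse = %.6g, %s penalty = %.6g, total = %.6g (lambda = %g)\n",
              x$mse, x$penalty_kind, x$penalty, x$total, x$lambda))
  invisible(x)
}

# Expanded-form stationary error, written with the lagged moments:
#   tr((FA - I) Sigma_x (FA - I)') + 2 tr((FA - I) E[x_t xhat_{t-1}'] G')
#   + tr(F C F') + tr(G E[xhat xhat'] G')
# Cross-check of mse_objective used in tests.
#' @keywords internal
mse_objective_expanded <- function(A, F_gain, G, prior, C) {
  m <- stationary_joint_moments(A, F_gain, G, prior, C)
  Sigma_x <- m$Sxx
  FA_I <- F_gain %*% A - diag(prior$n)
  sum(diag(FA_I %*% Sigma_x %*% t(FA_I))) +
    2 * sum(diag(FA_I %*% m$Sxh_lagged %*% t(G))) +
    sum(diag(F_gain %*% C %*% t(F_gain))) +
    sum(diag(G %*% m$Shh %*% t(G)))
}
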