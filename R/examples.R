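# Illustrative signal/noise covariance design problems.
#
# Two 6-channel, 1-DOF design problems with easily interpretable optima,
# specified purely by a (signal covariance, noise covariance) pair -- the
# sufficient statistics for the design when the trace-of-quotient penalty
# is evaluated against the fixed empirical covariance Sigma_sig + C.

#' Example signal/noise covariance pairs
#'
#' * Example 1: independent channels, equal signal power on all six, noise
#'   low on channels 2 and 5 -- the optimized pair should transmit along
#'   those two high-SNR channels.
#' * Example 2: rank-1 signal with power decreasing over channel index,
#'   same noise as example 1 -- the decoder should read out channels with
#'   high signal and low noise (channel 2 more strongly than channel 1).
#'
#' @param id 1 or 2
#' @param prior kinematic prior whose stationary variance scales the signal
#' @return list with `Sigma_sig`, `C`, `Sigma_y` (their sum), `prior`, `id`
#' @export
covariance_example <- function(id, prior = kinematic_prior(0.99, 0.01, 1)) {
  if (!id %in% 1:2) stop("id must be 1 or 2", call. = FALSE)
  sigma_x2 <- drop(solve_lyapunov(prior)$Sigma_x)
  C <- diag(c(1, 0.1, 1, 1, 0.1, 1))
  if (id == 1) {
    Sigma_sig <- diag(6)                     # equal unit signal power
  } else {
    v <- seq(1, 0.5, length.out = 6)         # decreasing rank-1 signal
    Sigma_sig <- v %*% t(v)
  }
  list(Sigma_sig = Sigma_sig, C = C, Sigma_y = Sigma_sig + C,
       prior = prior, id = id, sigma_x2 = sigma_x2)
}

#' Optimize an encoder-decoder pair from covariance sufficient statistics
#'
#' Runs the joint coordinate-descent optimization for a design problem
#' given only a signal/noise covariance pair: the trace-of-quotient penalty
#' is evaluated against the fixed empirical covariance
#' `Sigma_y = Sigma_sig + C` (calibration-covariance mode), which is what
#' makes the pair sufficient for the design.
#'
#' @param Sigma_sig k x k signal covariance
#' @param C k x k noise covariance
#' @param prior a [kinematic_prior()]
#' @param config an [optimizer_config()]
#' @return a canonicalized `optimization_result` (see [coordinate_descent()])
#' @export
optimize_from_covariances <- function(Sigma_sig, C,
                                      prior = kinematic_prior(0.99, 0.01, 1),
                                      config = optimizer_config()) {
  Sigma_sig <- as.matrix(Sigma_sig)
  k <- nrow(Sigma_sig)
  C <- as_matrix(C, k, "C")
  res <- coordinate_descent(prior, C, config = config,
                            Sigma_y_ref = Sigma_sig + C)
  canonicalize_solution(res)
}
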