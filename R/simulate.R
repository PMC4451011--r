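# Long stationary closed-loop simulation (intention -> channels -> decode).

#' Simulate the coupled intention/decoder process
#'
#' Samples the AR(1) intention, passes it through the encoder, and decodes
#' with the fixed `(F, G)` recursion, all in one compiled loop. Used to
#' check the analytic stationary moments and MSE against long empirical
#' averages.
#'
#' @param enc an [encoder()]
#' @param prior a [kinematic_prior()]
#' @param dec an `sskf_decoder` (or list with `F`, `G`)
#' @param T_steps number of steps
#' @param seed optional integer seed
#' @param x0 initial intention (default: stationary draw)
#' @param xhat0 initial decoded state (default zero, the stationary mean)
#' @param return_y also return the simulated neural channels
#' @return list with `x` and `xhat` (`T_steps` x n matrices), optionally `y`
#' @export
simulate_closed_loop <- function(enc, prior, dec, T_steps, seed = NULL,
                                 x0 = NULL, xhat0 = NULL, return_y = FALSE) {
  stopifnot(inherits(enc, "encoder"), inherits(prior, "kinematic_prior"))
  if (T_steps < 1) stop("T_steps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- prior$n
  if (is.null(x0)) {
    Sigma_x <- solve_lyapunov(prior)$Sigma_x
    x0 <- drop(t(chol_psd(Sigma_x)) %*% stats::rnorm(n))
  }
  if (is.null(xhat0)) xhat0 <- rep(0, n)
  Lq <- t(chol_psd(prior$Q))
  Lc <- t(chol(enc$C))
  cpp_closed_loop_trace(prior$P, Lq, enc$A, Lc,
                        as.matrix(dec$F), as_matrix(dec$G, n, "G"),
                        as.integer(T_steps), as.numeric(x0),
                        as.numeric(xhat0), return_y)
}

#' Empirical stationary MSE from a simulated trace
#' @param sim output of [simulate_closed_loop()]
#' @return scalar mean of the per-step squared error
#' @export
empirical_mse <- function(sim) {
  mean(rowSums((sim$xhat - sim$x)^2))
}
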