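# Linear-Gaussian encoding model: y_t = A x_t + eps_t, eps_t ~ N(0, C).
#
# A (k x n) is the user's encoding of intention into k neural channels and
# C the channel noise covariance. Two penalties constrain the encoded
# signal power: the trace-of-quotient penalty tr(Sigma_y^{-1} A Sigma_x A')
# (signal power relative to total neural covariance, bounded per generalized
# eigenvalue by 1) and the SNR penalty tr(C^{-1} A Sigma_x A') (unbounded --
# without it the mean-squared-error objective drives A to infinity).

#' Construct a linear-Gaussian encoder
#'
#' @param A k x n observation (encoding) matrix; a vector is taken as a
#'   single-column matrix (1-D control).
#' @param C k x k channel noise covariance, strictly positive definite, or a
#'   scalar/vector shorthand for a diagonal matrix.
#' @return an object of class `encoder` with fields `A`, `C`, `k`, `n`.
#' @examples
#' enc <- encoder(A = c(1, 0.5), C = diag(c(1, 0.1)))
#' @export
encoder <- function(A, C) {
  if (is.null(dim(A))) A <- matrix(as.numeric(A), ncol = 1)
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("A must be finite", call. = FALSE)
  k <- nrow(A)
  C <- as_matrix(C, k, "C")
  C <- sym(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("C must be strictly positive definite (invertible noise covariance)",
         call. = FALSE)
  structure(list(A = A, C = C, k = k, n = ncol(A)), class = "encoder")
}

#' @export
print.encoder <- function(x, ...) {
  cat(sprintf("linear-Gaussian encoder: k = %d channels, n = %d kinematic dims\n",
              x$k, x$n))
  invisible(x)
}

#' Signal, noise and total covariance of the neural channels
#'
#' @param enc an [encoder()]
#' @param Sigma_x stationary kinematic covariance (matrix or
#'   `stationary_covariance`)
#' @return list with `Sigma_sig = A Sigma_x A'`, `Sigma_y = Sigma_sig + C`
#' @export
neural_statistics <- function(enc, Sigma_x) {
  stopifnot(inherits(enc, "encoder"))
  Sigma_x <- get_sigma_x(Sigma_x, enc$n)
  Sigma_sig <- sym(enc$A %*% Sigma_x %*% t(enc$A))
  list(Sigma_sig = Sigma_sig, Sigma_y = Sigma_sig + enc$C)
}

#' @keywords internal
get_sigma_x <- function(Sigma_x, n) {
  if (inherits(Sigma_x, "stationary_covariance")) Sigma_x <- Sigma_x$Sigma_x
  if (inherits(Sigma_x, "kinematic_prior")) Sigma_x <- solve_lyapunov(Sigma_x)$Sigma_x
  as_matrix(Sigma_x, n, "Sigma_x")
}

#' Simulate a neural response to an intention
#'
#' Returns `A x + eps` with `eps ~ N(0, C)`. With `noise = FALSE` the
#' deterministic mean response is returned (used for noise-disabled
#' simulation checks).
#'
#' @param enc an [encoder()]
#' @param x intention vector (length n) or a T x n matrix of intentions
#' @param seed optional integer seed
#' @param noise logical, draw the additive Gaussian noise (default TRUE)
#' @return a k-vector, or a T x k matrix when `x` is a matrix
#' @export
neural_response <- function(enc, x, seed = NULL, noise = TRUE) {
  stopifnot(inherits(enc, "encoder"))
  if (!is.null(seed)) set.seed(seed)
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(X) != enc$n) stop("x has wrong dimension", call. = FALSE)
  Y <- X %*% t(enc$A)
  if (noise) {
    R_c <- chol(enc$C)
    Y <- Y + matrix(stats::rnorm(nrow(X) * enc$k), nrow(X), enc$k) %*% R_c
  }
  if (single) drop(Y) else Y
}

#' Trace-of-quotient penalty on the encoded signal power
#'
#' `tr(Sigma_y^{-1} A Sigma_x A')` with, by default, the model-implied total
#' covariance `Sigma_y = A Sigma_x A' + C`. Each generalized eigenvalue of
#' (signal, total) covariance lies in `[0, 1)`, so the value is bounded by
#' `min(k, n)`. Supplying `Sigma_y_ref` (e.g. an empirically calibrated
#' covariance) holds the denominator fixed, making the penalty quadratic in
#' `A`; this is how calibration covariances act as sufficient statistics for
#' the design problem.
#'
#' @param enc an [encoder()]
#' @param Sigma_x stationary kinematic covariance
#' @param Sigma_y_ref optional fixed k x k reference total covariance
#' @return scalar penalty value
#' @export
penalty_joint <- function(enc, Sigma_x, Sigma_y_ref = NULL) {
  stopifnot(inherits(enc, "encoder"))
  Sigma_x <- get_sigma_x(Sigma_x, enc$n)
  stats <- neural_statistics(enc, Sigma_x)
  Sy <- if (is.null(Sigma_y_ref)) stats$Sigma_y else as_matrix(Sigma_y_ref, enc$k, "Sigma_y_ref")
  # symmetric solve via Cholesky, never an explicit inverse
  R <- chol(Sy)
  sum(diag(chol2inv(R) %*% stats$Sigma_sig))
}

#' Signal-to-noise penalty on the encoded signal power
#'
#' `tr(C^{-1} A Sigma_x A')`: total encoded signal power weighted by inverse
#' channel noise. Unbounded above, degree-2 homogeneous in `A`.
#'
#' @inheritParams penalty_joint
#' @return scalar penalty value (>= 0)
#' @export
penalty_snr <- function(enc, Sigma_x) {
  stopifnot(inherits(enc, "encoder"))
  Sigma_x <- get_sigma_x(Sigma_x, enc$n)
  S <- sym(enc$A %*% Sigma_x %*% t(enc$A))
  R <- chol(enc$C)
  sum(diag(chol2inv(R) %*% S))
}
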