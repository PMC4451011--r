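# Steady-state Kalman filter (SSKF) decoder.
#
# For the linear-Gaussian model (prior P, Q; encoder A, C) the Kalman filter
# gain converges to a fixed value; the resulting decoder is the recursion
#   xhat_t = F y_t + G xhat_{t-1},
# with F = Sigma_SS A' (A Sigma_SS A' + C)^{-1}, G = P - F A P, and Sigma_SS
# the stabilizing solution of the discrete algebraic Riccati equation
#   Sigma_SS = P (Sigma_SS - Sigma_SS A' (A Sigma_SS A' + C)^{-1} A Sigma_SS) P' + Q.

#' Solve for the steady-state Kalman filter decoder
#'
#' Solves the filter-form discrete algebraic Riccati equation by a structured
#' doubling algorithm (quadratically convergent), falling back to the plain
#' fixed-point iteration if doubling stalls. The fixed-point iteration is
#' also exposed via `method = "iterate"` as an independent cross-check.
#'
#' @param enc an [encoder()] (A, C)
#' @param prior a [kinematic_prior()] (P, Q)
#' @param method `"doubling"` (default) or `"iterate"`
#' @param tol convergence tolerance on the Riccati residual
#' @param max_iter iteration cap (applies to `"iterate"`)
#' @return an object of class `sskf_decoder` with fields `F` (n x k gain),
#'   `G` (n x n recursion matrix), `Sigma_SS` (steady-state prior-error
#'   covariance), plus the model matrices for reference.
#' @examples
#' prior <- kinematic_prior(P = 0.9, Q = 0.19, n = 1)
#' enc <- encoder(A = 1, C = 1)
#' dec <- solve_sskf(enc, prior)   # Sigma_SS = sqrt(0.19)
#' @export
solve_sskf <- function(enc, prior, method = c("doubling", "iterate"),
                       tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(enc, "encoder"), inherits(prior, "kinematic_prior"))
  if (enc$n != prior$n) stop("encoder and prior dimensions disagree", call. = FALSE)
  method <- match.arg(method)
  Sigma <- switch(method,
    doubling = dare_doubling(prior$P, enc$A, enc$C, prior$Q),
    iterate  = riccati_iterate(prior$P, enc$A, enc$C, prior$Q,
                               tol = tol, max_iter = max_iter))
  Sigma <- sym(Sigma)
  res <- riccati_residual(Sigma, prior$P, enc$A, enc$C, prior$Q)
  if (res > 1e-8 * (1 + norm(Sigma, "F"))) {
    # doubling stalled (can happen for near-singular setups): fall back
    Sigma <- riccati_iterate(prior$P, enc$A, enc$C, prior$Q,
                             tol = tol, max_iter = max_iter)
    res <- riccati_residual(Sigma, prior$P, enc$A, enc$C, prior$Q)
    if (res > 1e-8 * (1 + norm(Sigma, "F")))
      stop(sprintf("Riccati solve failed to converge: residual %.3e", res),
           call. = FALSE)
  }
  S_y <- sym(enc$A %*% Sigma %*% t(enc$A) + enc$C)
  F_gain <- t(solve(S_y, enc$A %*% Sigma))      # Sigma A' S_y^{-1}
  G <- prior$P - F_gain %*% enc$A %*% prior$P
  structure(list(F = F_gain, G = G, Sigma_SS = Sigma,
                 A = enc$A, C = enc$C, P = prior$P, Q = prior$Q),
            class = "sskf_decoder")
}

#' @export
print.sskf_decoder <- function(x, ...) {
  cat(sprintf("steady-state Kalman filter decoder: n = %d, k = %d, spectral radius(G) = %.4f\n",
              nrow(x$F), ncol(x$F), spectral_radius(x$G)))
  invisible(x)
}

#' @keywords internal
riccati_residual <- function(Sigma, P, A, C, Q) {
  S_y <- sym(A %*% Sigma %*% t(A) + C)
  upd <- Sigma - Sigma %*% t(A) %*% solve(S_y, A %*% Sigma)
  norm(P %*% upd %*% t(P) + Q - Sigma, "F")
}

# Fixed-point iteration of the filter Riccati recursion, started at Q.
# Linearly convergent; retained as the independent oracle for the doubling
# solver and as its fallback.
#' @keywords internal
riccati_iterate <- function(P, A, C, Q, tol = 1e-12, max_iter = 1e5) {
  Sigma <- sym(Q)
  for (i in seq_len(max_iter)) {
    S_y <- sym(A %*% Sigma %*% t(A) + C)
    upd <- Sigma - Sigma %*% t(A) %*% solve(S_y, A %*% Sigma)
    Sigma_new <- sym(P %*% upd %*% t(P) + Q)
    if (max(abs(Sigma_new - Sigma)) < tol * (1 + max(abs(Sigma_new))))
      return(Sigma_new)
    Sigma <- Sigma_new
  }
  stop(sprintf("Riccati fixed-point iteration did not converge within %d iterations (residual %.3e)",
               max_iter, riccati_residual(Sigma, P, A, C, Q)), call. = FALSE)
}

# Structured doubling algorithm for the filter-form DARE.  With the
# correspondence (transition P, observation A, obs. noise C, proc. noise Q)
# -> control DARE data (A_d = P', B = A', R = C, Q_d = Q), iterate
#   A_{j+1} = A_j (I + G_j H_j)^{-1} A_j
#   G_{j+1} = G_j + A_j (I + G_j H_j)^{-1} G_j A_j'
#   H_{j+1} = H_j + A_j' H_j (I + G_j H_j)^{-1} A_j
# with A_0 = A_d, G_0 = B R^{-1} B', H_0 = Q_d; H_j -> Sigma_SS quadratically.
#' @keywords internal
dare_doubling <- function(P, A, C, Q, tol = 1e-14, max_iter = 200) {
  Ad <- t(P)
  G <- sym(t(A) %*% solve(C, A))
  H <- sym(Q)
  I_n <- diag(nrow(P))
  for (j in seq_len(max_iter)) {
    W <- I_n + G %*% H
    WinvA <- solve(W, Ad)
    A_new <- Ad %*% WinvA
    G_new <- sym(G + Ad %*% solve(W, G) %*% t(Ad))
    H_new <- sym(H + t(Ad) %*% H %*% WinvA)
    if (max(abs(H_new - H)) < tol * (1 + max(abs(H_new)))) return(H_new)
    Ad <- A_new; G <- G_new; H <- H_new
  }
  H
}

#' One SSKF decoding step
#'
#' Pure function: returns `F y + G xhat_prev`.
#'
#' @param dec an `sskf_decoder` (or any list with matrices `F` and `G`)
#' @param y neural observation, length k
#' @param xhat_prev previous decoded state, length n
#' @return decoded state, length n
#' @export
decode_step <- function(dec, y, xhat_prev) {
  y <- as.numeric(y); xhat_prev <- as.numeric(xhat_prev)
  if (length(y) != ncol(dec$F) || length(xhat_prev) != nrow(dec$G))
    stop("dimension mismatch in decode_step", call. = FALSE)
  drop(dec$F %*% y + dec$G %*% xhat_prev)
}

#' Decode a sequence of neural observations
#'
#' Batch application of [decode_step()] along the rows of `ys`.
#'
#' @param dec an `sskf_decoder`
#' @param ys T x k matrix of observations (nonempty)
#' @param xhat0 initial decoded state (default zero, the stationary mean)
#' @return T x n matrix of decoded states
#' @export
decode_sequence <- function(dec, ys, xhat0 = NULL) {
  ys <- as.matrix(ys)
  if (nrow(ys) < 1) stop("ys must be nonempty", call. = FALSE)
  n <- nrow(dec$G)
  if (is.null(xhat0)) xhat0 <- rep(0, n)
  X <- matrix(0, nrow(ys), n)
  x <- as.numeric(xhat0)
  for (t in seq_len(nrow(ys))) {
    x <- decode_step(dec, ys[t, ], x)
    X[t, ] <- x
  }
  X
}

# Time-varying Kalman filter gain sequence, initialized at the stationary
# prior covariance.  Test oracle: the gain converges to the SSKF gain F.
#' @keywords internal
kf_gain_sequence <- function(enc, prior, n_steps = 500) {
  Sigma <- solve_lyapunov(prior)$Sigma_x
  gains <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    S_y <- sym(enc$A %*% Sigma %*% t(enc$A) + enc$C)
    K <- t(solve(S_y, enc$A %*% Sigma))
    gains[[t]] <- K
    post <- Sigma - K %*% enc$A %*% Sigma
    Sigma <- sym(prior$P %*% post %*% t(prior$P) + prior$Q)
  }
  gains
}
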