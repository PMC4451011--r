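# Joint encoder-decoder optimization by coordinate descent.
#
# The penalized objective L(A, F, G) = MSE + lambda * penalty is descended
# by alternating (i) a gradient-based update of the encoding matrix A at
# fixed decoder (F, G) and (ii) the exact SSKF solve for (F, G) at fixed A.
# Both steps can only decrease L, so the per-iteration objective trace is
# monotone non-increasing.  The gradient of the stationary MSE with respect
# to A is obtained by the adjoint method through the augmented Lyapunov
# equation: with S solving S = M S M' + W and Lambda the adjoint solving
# Lambda = M' Lambda M + L_sel (L_sel the error-selection matrix), the
# differential is  d mse = 2 tr(S M' Lambda dM) + tr(Lambda dW).

#' Optimizer configuration
#'
#' @param lambda penalty weight (>= 0)
#' @param penalty_kind `"joint"` (trace-of-quotient, default) or `"snr"`
#' @param max_outer_iters cap on coordinate-descent alternations
#' @param outer_tol relative objective-change stopping threshold
#' @param inner_max_iters cap on gradient steps in each A-update
#' @param inner_method `"lbfgs"` (default, quasi-Newton with analytic
#'   gradient and a monotonicity safeguard) or `"armijo"` (plain gradient
#'   descent with backtracking line search)
#' @param grad_tol gradient-norm stopping threshold for the A-update
#' @param init_penalty_frac initial encoders are rescaled so the joint
#'   penalty equals this fraction of its saturation value `n`
#' @param n_restarts number of seeded random restarts (best objective kept)
#' @param seed base integer seed
#' @return list of class `optimizer_config`
#' @export
optimizer_config <- function(lambda = 1, penalty_kind = c("joint", "snr"),
                             max_outer_iters = 500, outer_tol = 1e-8,
                             inner_max_iters = 200,
                             inner_method = c("lbfgs", "armijo"),
                             grad_tol = 1e-9, init_penalty_frac = 0.5,
                             n_restarts = 5, seed = 1) {
  penalty_kind <- match.arg(penalty_kind)
  inner_method <- match.arg(inner_method)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (outer_tol <= 0 || grad_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (max_outer_iters < 1 || inner_max_iters < 1 || n_restarts < 1)
    stop("iteration counts must be >= 1", call. = FALSE)
  structure(list(lambda = lambda, penalty_kind = penalty_kind,
                 max_outer_iters = max_outer_iters, outer_tol = outer_tol,
                 inner_max_iters = inner_max_iters, inner_method = inner_method,
                 grad_tol = grad_tol, init_penalty_frac = init_penalty_frac,
                 n_restarts = n_restarts, seed = seed),
            class = "optimizer_config")
}

#' Gradient of the penalized objective with respect to the encoder
#'
#' Gradient of [full_objective()] in `A` at fixed decoder `(F, G)`,
#' accounting for the dependence of the stationary joint moments on `A`
#' (through both the augmented transition and the injected noise terms).
#' Computed by the adjoint method (two Lyapunov solves), and validated
#' against central finite differences in the test suite.
#'
#' @inheritParams full_objective
#' @return k x n gradient matrix
#' @export
grad_objective_wrt_A <- function(A, F_gain, G, prior, C, lambda = 1,
                                 penalty_kind = c("joint", "snr"),
                                 Sigma_y_ref = NULL) {
  penalty_kind <- match.arg(penalty_kind)
  n <- prior$n
  A <- as.matrix(A); F_gain <- as.matrix(F_gain); G <- as_matrix(G, n, "G")
  sys <- augmented_system(A, F_gain, G, prior, C)
  if (spectral_radius(sys$M) >= 1)
    stop("augmented system is unstable at A", call. = FALSE)
  S <- dlyap(sys$M, sys$W)
  I_n <- diag(n)
  L_sel <- rbind(cbind(I_n, -I_n), cbind(-I_n, I_n))
  Lambda <- dlyap(t(sys$M), L_sel)          # adjoint Lyapunov equation
  ix <- seq_len(n); ih <- n + seq_len(n)
  K <- S %*% t(sys$M) %*% Lambda
  L12 <- Lambda[ix, ih, drop = FALSE]
  L22 <- Lambda[ih, ih, drop = FALSE]
  grad_mse <- 2 * t(F_gain) %*% t(K[ix, ih, drop = FALSE]) %*% t(prior$P) +
              2 * t(F_gain) %*% t(L12) %*% prior$Q +
              2 * t(F_gain) %*% L22 %*% F_gain %*% A %*% prior$Q
  Sigma_x <- solve_lyapunov(prior)$Sigma_x
  grad_pen <- if (penalty_kind == "snr") {
    2 * solve(C, A %*% Sigma_x)
  } else if (!is.null(Sigma_y_ref)) {
    2 * solve(as_matrix(Sigma_y_ref, nrow(A), "Sigma_y_ref"), A %*% Sigma_x)
  } else {
    Sy <- sym(A %*% Sigma_x %*% t(A) + C)
    Z <- solve(Sy, C) %*% solve(Sy)         # Sy^{-1} C Sy^{-1}
    2 * sym(Z) %*% A %*% Sigma_x
  }
  grad_mse + lambda * grad_pen
}

#' Optimize the encoder at a fixed decoder
#'
#' Descends [full_objective()] in `A` with `(F, G)` held fixed. The default
#' quasi-Newton path uses `stats::optim(method = "L-BFGS-B")` with the
#' analytic gradient; the returned encoder never has a larger objective than
#' the start (the start is kept, with `warning_flag = TRUE`, if no
#' improvement is found). An Armijo backtracking gradient-descent path is
#' available for cross-checking.
#'
#' @param A_init starting k x n encoding matrix
#' @inheritParams full_objective
#' @param config an [optimizer_config()]
#' @return list with `A`, `value` (final total objective), `warning_flag`
#' @export
optimize_encoder_given_decoder <- function(A_init, F_gain, G, prior, C,
                                           config = optimizer_config(),
                                           Sigma_y_ref = NULL) {
  A_init <- as.matrix(A_init)
  k <- nrow(A_init); n <- ncol(A_init)
  fn <- function(a) {
    full_objective(matrix(a, k, n), F_gain, G, prior, C,
                   lambda = config$lambda, penalty_kind = config$penalty_kind,
                   Sigma_y_ref = Sigma_y_ref)$total
  }
  gr <- function(a) {
    as.vector(grad_objective_wrt_A(matrix(a, k, n), F_gain, G, prior, C,
                                   lambda = config$lambda,
                                   penalty_kind = config$penalty_kind,
                                   Sigma_y_ref = Sigma_y_ref))
  }
  f0 <- fn(as.vector(A_init))
  g0 <- gr(as.vector(A_init))
  if (sqrt(sum(g0^2)) < config$grad_tol)
    return(list(A = A_init, value = f0, warning_flag = FALSE))
  if (config$inner_method == "lbfgs") {
    res <- stats::optim(as.vector(A_init), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$inner_max_iters,
                                       factr = 1e4))
    if (res$value <= f0) {
      return(list(A = matrix(res$par, k, n), value = res$value,
                  warning_flag = FALSE))
    }
    # fall through to the safeguarded line search from the start point
  }
  # Armijo backtracking gradient descent
  A <- A_init; f <- f0
  improved <- FALSE
  for (it in seq_len(config$inner_max_iters)) {
    g <- matrix(gr(as.vector(A)), k, n)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < config$grad_tol) break
    step <- 1e-2 / (1 + gnorm) * max(1, sqrt(sum(A^2)))
    accepted <- FALSE
    for (ls in 1:40) {
      A_try <- A - step * g
      f_try <- fn(as.vector(A_try))
      if (f_try <= f - 1e-4 * step * gnorm^2) { accepted <- TRUE; break }
      step <- step * 0.5
    }
    if (!accepted) break
    A <- A_try; f <- f_try; improved <- TRUE
  }
  list(A = A, value = f, warning_flag = !improved)
}

#' @keywords internal
initial_encoder <- function(k, n, prior, C, config, Sigma_y_ref = NULL) {
  A0 <- matrix(stats::rnorm(k * n), k, n)
  Sigma_x <- solve_lyapunov(prior)$Sigma_x
  target <- config$init_penalty_frac * n
  pen_at <- function(s) {
    if (config$penalty_kind == "snr")
      penalty_snr(encoder(s * A0, C), Sigma_x)
    else
      penalty_joint(encoder(s * A0, C), Sigma_x, Sigma_y_ref = Sigma_y_ref)
  }
  # penalty is monotone increasing in the overall scale; bisect on log-scale
  lo <- 1e-6; hi <- 1
  while (pen_at(hi) < target && hi < 1e6) hi <- hi * 2
  if (pen_at(hi) < target) return(hi * A0)
  s <- stats::uniroot(function(u) pen_at(exp(u)) - target,
                      lower = log(lo), upper = log(hi))$root
  exp(s) * A0
}

#' Jointly optimize encoder and decoder by coordinate descent
#'
#' Alternates [optimize_encoder_given_decoder()] (A-update) with
#' [solve_sskf()] ((F, G)-update) until the relative change of the penalized
#' objective falls below `config$outer_tol`. Runs `config$n_restarts` seeded
#' random initializations and keeps the best final objective. The
#' per-outer-iteration objective trace is monotone non-increasing because
#' each half-step is a descent step.
#'
#' @param prior a [kinematic_prior()]
#' @param C k x k channel noise covariance
#' @param k number of neural channels (inferred from `C` when a matrix)
#' @param config an [optimizer_config()]
#' @param Sigma_y_ref optional fixed reference covariance for the joint
#'   penalty (calibration-covariance mode, see [penalty_joint()])
#' @param A_init optional fixed starting encoder (disables random restarts)
#' @return list of class `optimization_result`: `A`, `decoder` (the matched
#'   `sskf_decoder`), `objective` (final `objective_value`),
#'   `objective_trace` (data frame of per-iteration mse/penalty/total),
#'   `converged`, `iterations`, `seed`, `restarts` (all restart summaries)
#' @export
coordinate_descent <- function(prior, C, k = NULL, config = optimizer_config(),
                               Sigma_y_ref = NULL, A_init = NULL) {
  stopifnot(inherits(prior, "kinematic_prior"))
  if (is.null(k)) {
    if (is.null(dim(C))) stop("supply k when C is given as a scalar/vector", call. = FALSE)
    k <- nrow(C)
  }
  C <- as_matrix(C, k, "C")
  if (min(eigen(sym(C), symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("C must be positive definite", call. = FALSE)
  n <- prior$n
  restarts <- if (is.null(A_init)) config$n_restarts else 1L
  all_runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    seed_r <- config$seed + (r - 1L)
    set.seed(seed_r)
    A <- if (is.null(A_init)) {
      initial_encoder(k, n, prior, C, config, Sigma_y_ref)
    } else as.matrix(A_init)
    dec <- solve_sskf(encoder(A, C), prior)
    obj <- full_objective(A, dec$F, dec$G, prior, C, lambda = config$lambda,
                          penalty_kind = config$penalty_kind,
                          Sigma_y_ref = Sigma_y_ref)
    trace <- list(data.frame(iter = 0, mse = obj$mse, penalty = obj$penalty,
                             total = obj$total))
    converged <- FALSE; iters <- 0L
    for (it in seq_len(config$max_outer_iters)) {
      upd <- optimize_encoder_given_decoder(A, dec$F, dec$G, prior, C,
                                            config = config,
                                            Sigma_y_ref = Sigma_y_ref)
      A <- upd$A
      dec <- solve_sskf(encoder(A, C), prior)
      obj_new <- full_objective(A, dec$F, dec$G, prior, C,
                                lambda = config$lambda,
                                penalty_kind = config$penalty_kind,
                                Sigma_y_ref = Sigma_y_ref)
      iters <- it
      trace[[it + 1L]] <- data.frame(iter = it, mse = obj_new$mse,
                                     penalty = obj_new$penalty,
                                     total = obj_new$total)
      rel_change <- abs(obj$total - obj_new$total) / (abs(obj$total) + 1e-300)
      obj <- obj_new
      if (rel_change < config$outer_tol) { converged <- TRUE; break }
    }
    all_runs[[r]] <- list(A = A, decoder = dec, objective = obj,
                          objective_trace = do.call(rbind, trace),
                          converged = converged, iterations = iters,
                          seed = seed_r)
  }
  best <- which.min(vapply(all_runs, function(z) z$objective$total, 0))
  out <- all_runs[[best]]
  out$restarts <- lapply(all_runs, function(z)
    list(seed = z$seed, total = z$objective$total, converged = z$converged,
         iterations = z$iterations))
  class(out) <- "optimization_result"
  out
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("joint encoder-decoder optimum: k = %d, n = %d\n",
              nrow(x$A), ncol(x$A)))
  print(x$objective)
  cat(sprintf("converged: %s after %d outer iterations (%d restart(s))\n",
              x$converged, x$iterations, length(x$restarts)))
  invisible(x)
}

#' Optimal encoder and static linear decoder (marginal problem)
#'
#' Solves the penalized design problem when the decoder is restricted to the
#' static form `xhat_t = F y_t` (no recursion), i.e. each time step treated
#' as an i.i.d. Gaussian draw with covariance `Sigma_x` -- the classical
#' robust-coding problem. For fixed `A` the optimal static decoder is the
#' Wiener gain `F = Sigma_x A' (A Sigma_x A' + C)^{-1}`; the encoder is
#' updated by L-BFGS on the exact marginal objective. In the limit of a
#' vanishing transition matrix the full Kalman-decoder solution reduces to
#' this marginal solution.
#'
#' @param Sigma_x n x n marginal kinematic covariance (matrix or
#'   `stationary_covariance`)
#' @param C k x k channel noise covariance
#' @param k channel count (inferred from `C` when a matrix)
#' @param config an [optimizer_config()]
#' @param A_init optional fixed starting encoder
#' @return list with `A`, `F` (static decoder), `objective` (list with mse,
#'   penalty, total), `objective_trace`, `converged`, `iterations`
#' @export
static_decoder_solution <- function(Sigma_x, C, k = NULL,
                                    config = optimizer_config(),
                                    A_init = NULL) {
  if (inherits(Sigma_x, "stationary_covariance")) Sigma_x <- Sigma_x$Sigma_x
  Sigma_x <- as.matrix(Sigma_x)
  n <- nrow(Sigma_x)
  if (is.null(k)) {
    if (is.null(dim(C))) stop("supply k when C is given as a scalar/vector", call. = FALSE)
    k <- nrow(C)
  }
  C <- as_matrix(C, k, "C")
  wiener <- function(A) t(solve(sym(A %*% Sigma_x %*% t(A) + C), A %*% Sigma_x))
  pen <- function(A) {
    enc <- encoder(A, C)
    if (config$penalty_kind == "snr") penalty_snr(enc, Sigma_x)
    else penalty_joint(enc, Sigma_x)
  }
  mse_static <- function(A, F_gain) {
    FA_I <- F_gain %*% A - diag(n)
    sum(diag(FA_I %*% Sigma_x %*% t(FA_I))) +
      sum(diag(F_gain %*% C %*% t(F_gain)))
  }
  grad_pen <- function(A) {
    if (config$penalty_kind == "snr") return(2 * solve(C, A %*% Sigma_x))
    Sy <- sym(A %*% Sigma_x %*% t(A) + C)
    2 * sym(solve(Sy, C) %*% solve(Sy)) %*% A %*% Sigma_x
  }
  set.seed(config$seed)
  A <- if (is.null(A_init)) {
    # reuse the penalty-scaled random initialization via a throwaway prior
    # with the requested marginal covariance (P = 0 gives Sigma_x = Q)
    initial_encoder(k, n, kinematic_prior(matrix(0, n, n), Sigma_x, n), C, config)
  } else as.matrix(A_init)
  F_gain <- wiener(A)
  total <- function(A, F_gain) mse_static(A, F_gain) + config$lambda * pen(A)
  obj <- total(A, F_gain)
  trace <- c(obj)
  converged <- FALSE; iters <- 0L
  for (it in seq_len(config$max_outer_iters)) {
    fn <- function(a) total(matrix(a, k, n), F_gain)
    gr <- function(a) {
      Amat <- matrix(a, k, n)
      g_mse <- 2 * t(F_gain) %*% (F_gain %*% Amat - diag(n)) %*% Sigma_x
      as.vector(g_mse + config$lambda * grad_pen(Amat))
    }
    res <- stats::optim(as.vector(A), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$inner_max_iters,
                                       factr = 1e4))
    if (res$value <= fn(as.vector(A))) A <- matrix(res$par, k, n)
    F_gain <- wiener(A)
    obj_new <- total(A, F_gain)
    iters <- it
    trace <- c(trace, obj_new)
    rel_change <- abs(obj - obj_new) / (abs(obj) + 1e-300)
    obj <- obj_new
    if (rel_change < config$outer_tol) { converged <- TRUE; break }
  }
  list(A = A, F = F_gain,
       objective = list(mse = mse_static(A, F_gain), penalty = pen(A),
                        total = obj),
       objective_trace = trace, converged = converged, iterations = iters)
}

#' Calibrate the penalty weight to a target signal budget
#'
#' Chooses the penalty weight `lambda` so that the jointly optimized
#' encoder's penalty value equals `target_penalty` -- the Lagrange-multiplier
#' view of the constraint: larger `lambda` buys less signal power. Used to
#' tune the design objective to the SNR of a known synthetic-activity setup
#' (e.g. the native motor-imitation encoding's penalty value).
#'
#' The optimized penalty value is monotone non-increasing in `lambda`;
#' bisection on `log(lambda)` therefore converges.
#'
#' @param prior a [kinematic_prior()]
#' @param C channel noise covariance
#' @param target_penalty desired penalty value of the optimum (> 0)
#' @param Sigma_y_ref optional fixed reference covariance for the joint
#'   penalty
#' @param penalty_kind `"joint"` or `"snr"`
#' @param lambda_range search interval
#' @param tol relative tolerance on the achieved penalty
#' @param seed seed for the inner optimizations
#' @return the calibrated `lambda`
#' @export
calibrate_lambda <- function(prior, C, target_penalty, Sigma_y_ref = NULL,
                             penalty_kind = "joint",
                             lambda_range = c(1e-3, 1e3), tol = 1e-3,
                             seed = 1) {
  if (target_penalty <= 0) stop("target_penalty must be > 0", call. = FALSE)
  pen_at <- function(loglam) {
    cfg <- optimizer_config(lambda = exp(loglam), penalty_kind = penalty_kind,
                            n_restarts = 1, seed = seed)
    res <- coordinate_descent(prior, C, config = cfg, Sigma_y_ref = Sigma_y_ref)
    res$objective$penalty
  }
  lo <- log(lambda_range[1]); hi <- log(lambda_range[2])
  f_lo <- pen_at(lo) - target_penalty   # penalty decreasing in lambda
  f_hi <- pen_at(hi) - target_penalty
  if (f_lo < 0) return(lambda_range[1])
  if (f_hi > 0) return(lambda_range[2])
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    f_mid <- pen_at(mid) - target_penalty
    if (abs(f_mid) < tol * target_penalty) return(exp(mid))
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Resolve the sign indeterminacy of an optimized pair
#'
#' The objective is invariant under jointly flipping the signs of `A` and
#' `F` (a global flip always; per-dimension flips whenever the prior's `P`
#' and `Q` are diagonal, as in the position-only control setting used
#' throughout). For each kinematic dimension `j`, this flips column `j` of
#' `A` and row `j` of `F` so that the largest-magnitude entry of the column
#' is positive, and conjugates `G` accordingly (`G -> D G D` with `D` the
#' diagonal sign matrix, which leaves a matched `G = P - F A P` matched).
#' Idempotent; the objective value is unchanged.
#'
#' @param result an `optimization_result`, or a list with `A` and either
#'   `decoder$F`/`decoder$G` or `F`/`G`
#' @return the input with canonicalized signs
#' @export
canonicalize_solution <- function(result) {
  A <- as.matrix(result$A)
  has_dec <- !is.null(result$decoder)
  F_gain <- if (has_dec) result$decoder$F else result$F
  G <- if (has_dec) result$decoder$G else result$G
  d <- rep(1, ncol(A))
  for (j in seq_len(ncol(A))) {
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) d[j] <- -1
  }
  D <- diag(d, ncol(A))
  A <- A %*% D
  if (!is.null(F_gain)) F_gain <- D %*% F_gain
  if (!is.null(G)) G <- D %*% G %*% D
  result$A <- A
  if (has_dec) {
    result$decoder$F <- F_gain
    result$decoder$G <- G
  } else {
    if (!is.null(F_gain)) result$F <- F_gain
    if (!is.null(G)) result$G <- G
  }
  result
}

#' Canonicalize the signs of an encoding matrix alone
#'
#' Flips each column of `A` so its largest-magnitude entry is positive.
#' Used before comparing encoder weight patterns, where the overall sign is
#' arbitrary.
#'
#' @param A encoding matrix (vector accepted for 1-D control)
#' @return matrix with canonical column signs
#' @export
canonicalize_encoder <- function(A) {
  if (is.null(dim(A))) A <- matrix(as.numeric(A), ncol = 1)
  A <- as.matrix(A)
  for (j in seq_len(ncol(A))) {
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) A[, j] <- -A[, j]
  }
  A
}
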