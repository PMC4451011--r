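# Online-prosthesis-simulator (OPS) emulator.
#
# Desk-scale analog of a human-in-the-loop prosthesis simulator: user
# intention drives k = 6 synthetic neural channels through a signal case
# (which movement features drive which channels, and how noisy each channel
# is), a fixed SSKF decoder maps channels to a 1-D cursor, and a simulated
# user adapts its encoding by gradient steps on the same penalized objective
# the joint optimizer descends.  Two decoder arms are compared: a
# "motor-imitation" decoder fit by recursive least squares to the user's
# naive biomimetic control scheme, and the "pre-computed" decoder from the
# joint encoder-decoder optimization.

# ---------------------------------------------------------------------------
# signal cases

#' Build one of the three canonical signal cases
#'
#' Each case specifies how m movement/intention features drive k = 6
#' simulated neural channels (one feature per driven channel; remaining
#' channels are pure noise) and the per-channel noise pattern. Noise is
#' "high" (1.0, the signal power of a heavily used channel) or "low"
#' (`low_frac` times that; 0.1 by default, a 10:1 power ratio).
#'
#' * Case 1: right-hand horizontal (high noise) and vertical (low noise).
#' * Case 2: both-hands-horizontal sum (high) and hands-distance (low).
#' * Case 3: each hand's horizontal (high) and vertical (low) positions.
#'
#' The biomimetic ("motor-imitation") strategy drives the horizontal
#' feature(s) in every case, so naive control uses high-noise channels. The
#' returned `A_motor` is the corresponding native encoding, scaled so each
#' heavily used channel has unit signal power under the default prior.
#'
#' @param id case id, 1, 2 or 3
#' @param seed optional seed recorded in the case (construction is
#'   deterministic)
#' @param prior the kinematic prior used to scale signal power
#' @param low_frac low-noise variance as a fraction of the high level
#' @return list of class `signal_case`: `id`, `k`, `m`, `mixing` (k x m),
#'   `noise_levels`, `features`, `biomimetic_features`, `A_motor`,
#'   `encoder_motor` (the motor-imitation probe encoder), `C`,
#'   `Sigma_y_cal` (calibration total covariance), `prior`, `seed`
#' @export
build_signal_case <- function(id, seed = NULL,
                              prior = kinematic_prior(0.99, 0.01, 1),
                              low_frac = 0.1) {
  if (!id %in% 1:3) stop("unknown signal case id (must be 1, 2 or 3)", call. = FALSE)
  k <- 6L
  high <- 1.0; low <- low_frac * high
  if (id == 1) {
    features <- c("right_hand_horizontal", "right_hand_vertical")
    driven <- c(1L, 2L)                      # channel i <- feature i
    noise <- c(high, low, high, high, high, high)
    biomimetic <- 1L
  } else if (id == 2) {
    features <- c("hands_sum_horizontal", "hands_distance")
    driven <- c(1L, 2L)
    noise <- c(high, low, high, high, high, high)
    biomimetic <- 1L
  } else {
    features <- c("left_hand_horizontal", "right_hand_horizontal",
                  "left_hand_vertical", "right_hand_vertical")
    driven <- c(1L, 2L, 3L, 4L)
    noise <- c(high, high, low, low, high, high)
    biomimetic <- c(1L, 2L)
  }
  m <- length(features)
  mixing <- matrix(0, k, m)
  for (j in seq_len(m)) mixing[driven[j], j] <- 1
  # scale so a heavily used channel has signal power equal to the high noise
  sigma_x2 <- drop(solve_lyapunov(prior)$Sigma_x)
  g <- sqrt(high / sigma_x2)
  u_mi <- rep(0, m); u_mi[biomimetic] <- g
  A_motor <- mixing %*% matrix(u_mi, ncol = 1)
  C <- diag(noise)
  # calibration covariance: all features active at natural magnitude
  Sigma_y_cal <- sigma_x2 * g^2 * (mixing %*% t(mixing)) + C
  structure(list(id = as.integer(id), k = k, m = m, mixing = mixing,
                 noise_levels = noise, features = features,
                 biomimetic_features = biomimetic, A_motor = A_motor,
                 encoder_motor = encoder(A_motor, C), C = C,
                 Sigma_y_cal = Sigma_y_cal, prior = prior, seed = seed),
            class = "signal_case")
}

#' @export
print.signal_case <- function(x, ...) {
  cat(sprintf("OPS signal case %d: k = %d channels, %d features (low noise on channel(s) %s)\n",
              x$id, x$k, x$m,
              paste(which(x$noise_levels == min(x$noise_levels)), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# task and user

#' Task specification for closed-loop sessions
#'
#' Times are in seconds; one step is `1 / sample_rate` seconds (10 Hz by
#' default, so the default session of 180 s is 1800 steps). The workspace is
#' the 1-D interval `[-1, 1]`. Pinball targets are placed uniformly at
#' random within `target_range` times the workspace half-width; tracing
#' targets follow an AR(1) path drawn from the prior.
#'
#' @param kind `"pinball"` (point-to-point reaching) or `"tracing"`
#'   (pursuit tracking)
#' @param sample_rate steps per second
#' @param hold_time seconds the cursor must stay within the halo to acquire
#' @param timeout seconds before an unacquired target counts as a miss
#' @param session_length session duration in seconds
#' @param halo_radius halo radius as a fraction of the workspace width
#' @param target_range pinball target placement range (fraction of half-width)
#' @return list of class `task_spec`
#' @export
task_spec <- function(kind = c("pinball", "tracing"), sample_rate = 10,
                      hold_time = 1.0, timeout = 15.0, session_length = 180,
                      halo_radius = 0.075, target_range = 0.85) {
  kind <- match.arg(kind)
  if (!(hold_time < timeout && timeout < session_length))
    stop("need hold_time < timeout < session_length", call. = FALSE)
  if (halo_radius <= 0) stop("halo_radius must be > 0", call. = FALSE)
  structure(list(kind = kind, sample_rate = sample_rate,
                 hold_time = hold_time, timeout = timeout,
                 session_length = session_length, halo_radius = halo_radius,
                 target_range = target_range, workspace = c(-1, 1)),
            class = "task_spec")
}

#' Simulated learning user
#'
#' The simulated user holds a current encoding `A_user` and, when
#' `update_rule = "gradient"`, improves it by line-searched gradient steps
#' on the penalized objective at the fixed decoder -- the idealized
#' counterpart of closed-loop user learning. Intention is the current
#' target position.
#'
#' @param A_user current k x n encoding matrix
#' @param learning_rate nonnegative step-size scale; 0 freezes the user
#' @param update_rule `"gradient"` or `"frozen"`
#' @param update_every learning cadence in steps during free exploration
#' @return list of class `simulated_user`
#' @export
simulated_user <- function(A_user, learning_rate = 1,
                           update_rule = c("gradient", "frozen"),
                           update_every = 10) {
  update_rule <- match.arg(update_rule)
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (learning_rate == 0) update_rule <- "frozen"
  A_user <- as.matrix(A_user)
  if (!all(is.finite(A_user))) stop("A_user must be finite", call. = FALSE)
  structure(list(A_user = A_user, learning_rate = learning_rate,
                 update_rule = update_rule, update_every = update_every),
            class = "simulated_user")
}

#' One user learning step at a fixed decoder
#'
#' Takes a single line-searched gradient step on
#' `full_objective(A_user, F, G)` with respect to `A_user`. The objective
#' never increases; if no improving step is found (or the gradient is
#' already below tolerance, or the learning rate is 0) the user is returned
#' unchanged.
#'
#' @param user a [simulated_user()]
#' @param dec the fixed `sskf_decoder`
#' @param prior a [kinematic_prior()]
#' @param C channel noise covariance
#' @param lambda,penalty_kind,Sigma_y_ref objective settings, as in
#'   [full_objective()]
#' @param grad_tol gradient norm below which the user is considered matched
#' @return the updated `simulated_user`
#' @export
user_learning_update <- function(user, dec, prior, C, lambda = 1,
                                 penalty_kind = "joint", Sigma_y_ref = NULL,
                                 grad_tol = 1e-8) {
  stopifnot(inherits(user, "simulated_user"))
  if (user$update_rule == "frozen" || user$learning_rate == 0) return(user)
  A <- user$A_user
  g <- grad_objective_wrt_A(A, dec$F, dec$G, prior, C, lambda = lambda,
                            penalty_kind = penalty_kind,
                            Sigma_y_ref = Sigma_y_ref)
  gnorm <- sqrt(sum(g^2))
  if (gnorm < grad_tol) return(user)
  f0 <- full_objective(A, dec$F, dec$G, prior, C, lambda = lambda,
                       penalty_kind = penalty_kind,
                       Sigma_y_ref = Sigma_y_ref)$total
  step <- user$learning_rate / (1 + gnorm)
  for (ls in 1:30) {
    A_try <- A - step * g
    f_try <- full_objective(A_try, dec$F, dec$G, prior, C, lambda = lambda,
                            penalty_kind = penalty_kind,
                            Sigma_y_ref = Sigma_y_ref)$total
    if (f_try <= f0 - 1e-4 * step * gnorm^2) {
      user$A_user <- A_try
      return(user)
    }
    step <- step / 2
  }
  user
}

# ---------------------------------------------------------------------------
# closed-loop sessions

#' Run one closed-loop OPS session
#'
#' At every step the user forms an intention (the current target position),
#' the intention drives the neural channels through the user's encoding
#' plus channel noise, and the fixed decoder updates the cursor. Pinball
#' sessions track hold/timeout logic and record acquisition and miss
#' events; tracing sessions follow an AR(1) target path. During a
#' `"exploration"` phase a gradient user updates its encoding every
#' `update_every` steps; during `"testing"` the user is frozen.
#'
#' @param user a [simulated_user()]
#' @param dec an `sskf_decoder`
#' @param case a [build_signal_case()] signal case
#' @param task a [task_spec()]
#' @param seed integer seed (recorded in the trace)
#' @param phase `"testing"` (default) or `"exploration"`
#' @param lambda,penalty_kind,Sigma_y_ref objective settings for user
#'   learning (exploration phase only)
#' @param noise logical; disable to run the deterministic mean path
#' @return list of class `session_trace`: `steps` (data frame with columns
#'   step, time_s, target, x_int, y_1..y_k, xhat, in_halo, event), `events`
#'   (data frame of acquisitions/misses with times), `task`, `seed`,
#'   `phase`, `A_user_final`
#' @export
run_closed_loop_session <- function(user, dec, case, task = task_spec(),
                                    seed = 1, phase = c("testing", "exploration"),
                                    lambda = 1, penalty_kind = "joint",
                                    Sigma_y_ref = NULL, noise = TRUE) {
  stopifnot(inherits(user, "simulated_user"), inherits(case, "signal_case"),
            inherits(task, "task_spec"))
  phase <- match.arg(phase)
  set.seed(seed)
  prior <- case$prior
  k <- case$k
  dt <- 1 / task$sample_rate
  T_steps <- round(task$session_length * task$sample_rate)
  hold_steps <- round(task$hold_time * task$sample_rate)
  timeout_steps <- round(task$timeout * task$sample_rate)
  halo <- task$halo_radius * diff(task$workspace)
  Lc <- t(chol(case$C))
  learning <- phase == "exploration" && user$update_rule == "gradient"

  new_target <- function() stats::runif(1, -task$target_range, task$target_range)
  if (task$kind == "tracing") {
    target_path <- drop(sample_trajectory(prior, T_steps))
  } else {
    target <- new_target()
  }

  xhat <- 0
  hold <- 0L; target_timer <- 0L
  tgt <- numeric(T_steps); xint <- numeric(T_steps); xh <- numeric(T_steps)
  inhalo <- logical(T_steps); event <- character(T_steps)
  Y <- matrix(0, T_steps, k)
  events <- list()

  for (t in seq_len(T_steps)) {
    if (task$kind == "tracing") target <- target_path[t]
    x <- target                             # intention = current target
    y <- drop(user$A_user %*% x)
    if (noise) y <- y + drop(Lc %*% stats::rnorm(k))
    xhat <- drop(dec$F %*% y + dec$G %*% xhat)
    if (abs(xhat) > 1e3)
      stop(sprintf("cursor diverged (|xhat| = %.3g at step %d): unstable decoder", xhat, t),
           call. = FALSE)
    # record the target/intention that generated this step's activity
    tgt[t] <- target
    xint[t] <- x; xh[t] <- xhat
    Y[t, ] <- y
    ev <- ""
    if (task$kind == "pinball") {
      target_timer <- target_timer + 1L
      if (abs(xhat - target) <= halo) hold <- hold + 1L else hold <- 0L
      inhalo[t] <- hold > 0L
      if (hold >= hold_steps) {
        ev <- "acquire"
        events[[length(events) + 1L]] <- data.frame(time_s = t * dt, type = "acquire")
        target <- new_target(); hold <- 0L; target_timer <- 0L
      } else if (target_timer >= timeout_steps) {
        ev <- "miss"
        events[[length(events) + 1L]] <- data.frame(time_s = t * dt, type = "miss")
        target <- new_target(); hold <- 0L; target_timer <- 0L
      }
    }
    event[t] <- ev
    if (learning && t %% user$update_every == 0L) {
      user <- user_learning_update(user, dec, prior, case$C, lambda = lambda,
                                   penalty_kind = penalty_kind,
                                   Sigma_y_ref = Sigma_y_ref)
    }
  }
  steps <- data.frame(step = seq_len(T_steps), time_s = seq_len(T_steps) * dt,
                      target = tgt, x_int = xint)
  colnames(Y) <- paste0("y_", seq_len(k))
  steps <- cbind(steps, Y)
  steps$xhat <- xh
  steps$in_halo <- inhalo
  steps$event <- event
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), type = character(0))
  structure(list(steps = steps, events = events, task = task, seed = seed,
                 phase = phase, case_id = case$id, A_user_final = user$A_user),
            class = "session_trace")
}

#' @export
print.session_trace <- function(x, ...) {
  n_acq <- sum(x$events$type == "acquire")
  n_miss <- sum(x$events$type == "miss")
  cat(sprintf("%s session (%gs, seed %s): %d acquisitions, %d misses\n",
              x$task$kind, x$task$session_length, format(x$seed), n_acq, n_miss))
  invisible(x)
}

# ---------------------------------------------------------------------------
# encoder estimation

#' Recursive least-squares fit of an encoding model
#'
#' Online linear regression from probe intentions to probe neural
#' responses, as used to initialize the motor-imitation decoder from an
#' open-loop tracing phase. The final estimate coincides with batch least
#' squares on the same data up to the (small) prior-precision
#' regularization.
#'
#' @param probe_intentions T x n matrix (or vector) of probe intentions
#' @param probe_neural T x k matrix of observed neural responses
#' @param delta prior precision initializing the RLS information matrix
#' @return estimated k x n encoding matrix
#' @export
rls_motor_imitation_init <- function(probe_intentions, probe_neural,
                                     delta = 1e-10) {
  X <- if (is.null(dim(probe_intentions))) matrix(probe_intentions, ncol = 1) else as.matrix(probe_intentions)
  Y <- as.matrix(probe_neural)
  n <- ncol(X); k <- ncol(Y)
  if (nrow(X) != nrow(Y)) stop("probe lengths disagree", call. = FALSE)
  if (nrow(X) < k * n) stop("need at least k*n probe samples", call. = FALSE)
  if (min(eigen(crossprod(X) / nrow(X), symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
    stop("rank-deficient probe intentions", call. = FALSE)
  P_rls <- diag(1 / delta, n)
  A_hat <- matrix(0, k, n)
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    Px <- drop(P_rls %*% x)
    denom <- 1 + sum(x * Px)
    K <- Px / denom
    err <- Y[t, ] - drop(A_hat %*% x)
    A_hat <- A_hat + outer(err, K)
    P_rls <- P_rls - outer(Px, Px) / denom
  }
  A_hat
}

#' Estimate the user's encoding model from a session
#'
#' Ordinary least squares of the neural channels on the target position
#' (the intention proxy: the user is assumed to steer straight at the
#' target), the same regression used to estimate encoders from task data.
#'
#' @param trace a `session_trace`
#' @return estimated k x n encoding matrix
#' @export
estimate_encoder_regression <- function(trace) {
  stopifnot(inherits(trace, "session_trace"))
  st <- trace$steps
  ycols <- grep("^y_", names(st))
  k <- length(ycols)
  if (nrow(st) < k) stop("trace too short for regression", call. = FALSE)
  x <- st$target
  if (stats::var(x) < 1e-12) stop("degenerate target variance", call. = FALSE)
  X <- matrix(x, ncol = 1)
  Y <- as.matrix(st[, ycols])
  unname(t(solve(crossprod(X), crossprod(X, Y))))
}

#' Correlation between two encoding weight patterns
#'
#' Pearson correlation of the flattened channel weights after column-sign
#' canonicalization of both matrices (the overall encoder sign carries no
#' information).
#'
#' @param A_est,A_opt same-shape encoding matrices
#' @return scalar correlation
#' @export
compare_encoders <- function(A_est, A_opt) {
  A1 <- canonicalize_encoder(A_est)
  A2 <- canonicalize_encoder(A_opt)
  if (!all(dim(A1) == dim(A2))) stop("encoder shapes disagree", call. = FALSE)
  v1 <- as.vector(A1); v2 <- as.vector(A2)
  if (stats::sd(v1) < 1e-14 || stats::sd(v2) < 1e-14)
    stop("zero-variance encoder weights", call. = FALSE)
  stats::cor(v1, v2)
}

# ---------------------------------------------------------------------------
# metrics

#' Point-to-point reaching metrics for a pinball session
#'
#' @param trace a pinball `session_trace`
#' @return list with `targets_acquired`, `targets_per_time` (per second),
#'   `targets_per_min`, `inter_acquisition_times` (seconds between
#'   consecutive acquisitions, the first measured from session start),
#'   `misses`
#' @export
pinball_metrics <- function(trace) {
  stopifnot(inherits(trace, "session_trace"))
  if (trace$task$kind != "pinball")
    stop("pinball_metrics requires a pinball-task trace", call. = FALSE)
  acq <- trace$events$time_s[trace$events$type == "acquire"]
  misses <- sum(trace$events$type == "miss")
  duration <- trace$task$session_length
  iat <- if (length(acq)) diff(c(0, acq)) else numeric(0)
  list(targets_acquired = length(acq),
       targets_per_time = length(acq) / duration,
       targets_per_min = 60 * length(acq) / duration,
       inter_acquisition_times = iat,
       misses = misses)
}

#' Compare decoder arms on inter-acquisition times
#'
#' Pools inter-acquisition times across sessions per arm and performs a
#' one-sided unpaired two-sample t-test (equal variances) of the hypothesis
#' that the pre-computed decoder acquires targets faster (shorter times)
#' than the motor-imitation decoder.
#'
#' @param traces_motor_imitation,traces_precomputed lists of pinball
#'   `session_trace`s, or numeric vectors of pooled inter-acquisition times
#' @param alpha significance level for the report flag
#' @return list with `t`, `df`, `p_value`, `significant`, per-arm sample
#'   sizes and mean times
#' @export
compare_decoders <- function(traces_motor_imitation, traces_precomputed,
                             alpha = 0.05) {
  pool <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    unlist(lapply(x, function(tr) pinball_metrics(tr)$inter_acquisition_times))
  }
  t_mi <- pool(traces_motor_imitation)
  t_pre <- pool(traces_precomputed)
  if (length(t_mi) < 2 || length(t_pre) < 2)
    stop("need at least 2 inter-acquisition samples per arm", call. = FALSE)
  tt <- stats::t.test(t_mi, t_pre, alternative = "greater", var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       n_motor = length(t_mi), n_precomputed = length(t_pre),
       mean_motor = mean(t_mi), mean_precomputed = mean(t_pre))
}

#' Autocorrelation function of the decoded cursor
#'
#' Sample ACF of the cursor position, normalized to 1 at lag 0. Faster
#' falloff indicates more responsive (less oversmoothed) control.
#'
#' @param trace a `session_trace`, or a numeric cursor series
#' @param max_lag largest lag (in steps)
#' @return numeric vector of length `max_lag + 1` (lags 0..max_lag)
#' @export
cursor_acf <- function(trace, max_lag = 50) {
  x <- if (inherits(trace, "session_trace")) trace$steps$xhat else as.numeric(trace)
  if (length(x) <= max_lag) stop("trace shorter than max_lag", call. = FALSE)
  if (stats::var(x) < 1e-14) stop("constant cursor: zero variance", call. = FALSE)
  drop(stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
}

# ---------------------------------------------------------------------------
# end-to-end comparison

#' Full two-arm OPS comparison on one signal case
#'
#' Builds the signal case; fits the motor-imitation decoder by an open-loop
#' RLS probe of the user's biomimetic encoding; computes the pre-computed
#' decoder by joint optimization against the calibration covariance; lets a
#' simulated gradient user learn each decoder; then runs `n_sessions`
#' frozen pinball testing sessions per arm and reports acquisition metrics,
#' the one-sided t-test on inter-acquisition times, cursor ACFs, and
#' learned-vs-optimal encoder correlations.
#'
#' @param case_id signal case, 1, 2 or 3
#' @param n_sessions testing sessions per arm
#' @param seed base integer seed
#' @param lambda penalty weight for the design objective; `NULL` (default)
#'   calibrates it so the optimized encoder's penalty matches the native
#'   motor-imitation encoding's penalty value (the user's SNR budget)
#' @param task a [task_spec()] (pinball)
#' @param n_learning_updates gradient user updates during learning
#' @param probe_steps open-loop probe length for the RLS fit
#' @return list of class `ops_comparison` with per-arm metrics and decoders
#' @export
run_ops_comparison <- function(case_id = 1, n_sessions = 20, seed = 1,
                               lambda = NULL, task = task_spec(),
                               n_learning_updates = 1000, probe_steps = 400) {
  case <- build_signal_case(case_id)
  prior <- case$prior
  Syr <- case$Sigma_y_cal
  if (is.null(lambda)) {
    Sigma_x <- solve_lyapunov(prior)$Sigma_x
    budget <- penalty_joint(case$encoder_motor, Sigma_x, Sigma_y_ref = Syr)
    lambda <- calibrate_lambda(prior, case$C, budget, Sigma_y_ref = Syr,
                               seed = seed)
  }

  # motor-imitation arm: open-loop probe -> RLS encoder fit -> SSKF
  set.seed(seed)
  probe_x <- sample_trajectory(prior, probe_steps)
  probe_y <- neural_response(case$encoder_motor, probe_x)
  A_mi_hat <- rls_motor_imitation_init(probe_x, probe_y)
  dec_mi <- solve_sskf(encoder(A_mi_hat, case$C), prior)

  # pre-computed arm: joint optimization against the calibration covariance
  opt <- coordinate_descent(prior, case$C,
                            config = optimizer_config(lambda = lambda,
                                                      n_restarts = 3,
                                                      seed = seed),
                            Sigma_y_ref = Syr)
  opt <- canonicalize_solution(opt)
  dec_pre <- opt$decoder

  # simulated user learning (idealized free-exploration phase)
  learn <- function(dec) {
    user <- simulated_user(case$A_motor)
    for (i in seq_len(n_learning_updates)) {
      user_new <- user_learning_update(user, dec, prior, case$C,
                                       lambda = lambda, Sigma_y_ref = Syr)
      if (identical(user_new$A_user, user$A_user) && i > 10) break
      user <- user_new
    }
    user
  }
  user_mi <- learn(dec_mi)
  user_pre <- learn(dec_pre)

  # optimal encoders for each fixed decoder (learning targets)
  opt_for <- function(dec, A_start) {
    optimize_encoder_given_decoder(A_start, dec$F, dec$G, prior, case$C,
                                   config = optimizer_config(lambda = lambda,
                                                             inner_max_iters = 500),
                                   Sigma_y_ref = Syr)$A
  }
  A_opt_mi <- opt_for(dec_mi, user_mi$A_user)
  A_opt_pre <- opt$A

  run_arm <- function(user, dec, offset) {
    user$update_rule <- "frozen"
    lapply(seq_len(n_sessions), function(s)
      run_closed_loop_session(user, dec, case, task,
                              seed = seed + offset + s))
  }
  traces_mi <- run_arm(user_mi, dec_mi, 1000L)
  traces_pre <- run_arm(user_pre, dec_pre, 2000L)

  metrics <- function(traces) {
    ms <- lapply(traces, pinball_metrics)
    list(targets_per_min = vapply(ms, function(m) m$targets_per_min, 0),
         iat = unlist(lapply(ms, function(m) m$inter_acquisition_times)),
         misses = vapply(ms, function(m) m$misses, 0),
         lag1_acf = vapply(traces, function(tr) cursor_acf(tr, 10)[2], 0))
  }
  m_mi <- metrics(traces_mi)
  m_pre <- metrics(traces_pre)
  ttest <- compare_decoders(m_mi$iat, m_pre$iat)

  structure(list(
    case = case,
    decoder_motor = dec_mi, decoder_precomputed = dec_pre,
    A_opt_motor = A_opt_mi, A_opt_precomputed = A_opt_pre,
    user_motor = user_mi, user_precomputed = user_pre,
    cor_motor = compare_encoders(user_mi$A_user, A_opt_mi),
    cor_precomputed = compare_encoders(user_pre$A_user, A_opt_pre),
    metrics_motor = m_mi, metrics_precomputed = m_pre,
    ttest = ttest,
    traces_motor = traces_mi, traces_precomputed = traces_pre,
    lambda = lambda, seed = seed), class = "ops_comparison")
}

#' @export
print.ops_comparison <- function(x, ...) {
  cat(sprintf("OPS comparison, signal case %d (%d sessions/arm):\n",
              x$case$id, length(x$traces_motor)))
  cat(sprintf("  targets/min: motor-imitation %.2f, pre-computed %.2f\n",
              mean(x$metrics_motor$targets_per_min),
              mean(x$metrics_precomputed$targets_per_min)))
  cat(sprintf("  inter-acquisition t-test (motor > pre-computed): t = %.2f, p = %.3g\n",
              x$ttest$t, x$ttest$p_value))
  cat(sprintf("  lag-1 cursor ACF: motor %.3f, pre-computed %.3f\n",
              mean(x$metrics_motor$lag1_acf), mean(x$metrics_precomputed$lag1_acf)))
  cat(sprintf("  learned-vs-optimal encoder correlation: motor %.3f, pre-computed %.3f\n",
              x$cor_motor, x$cor_precomputed))
  invisible(x)
}
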