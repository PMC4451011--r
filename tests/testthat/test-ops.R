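# OPS emulator: signal cases, sessions, learning, estimation, metrics.

test_that("signal cases implement the specified noise patterns", {
  for (id in 1:3) {
    case <- build_signal_case(id)
    expect_identical(case$k, 6L)
    expect_true(all(case$noise_levels > 0))
  }
  c1 <- build_signal_case(1)
  expect_identical(which(c1$noise_levels == min(c1$noise_levels)), 2L)
  expect_match(c1$features[2], "vertical")    # low noise on the vertical channel
  c2 <- build_signal_case(2)
  expect_identical(which(c2$noise_levels == min(c2$noise_levels)), 2L)
  expect_match(c2$features[2], "distance")    # hands-distance channel
  c3 <- build_signal_case(3)
  expect_identical(which(c3$noise_levels == min(c3$noise_levels)), c(3L, 4L))
  expect_error(build_signal_case(4), "unknown")
  # the native motor encoding drives only high-noise channels
  expect_true(all(c1$noise_levels[c1$A_motor != 0] == max(c1$noise_levels)))
})

test_that("closed-loop sessions are deterministic and converge without noise", {
  case <- build_signal_case(1)
  user <- simulated_user(case$A_motor, update_rule = "frozen")
  dec <- solve_sskf(case$encoder_motor, case$prior)
  task <- task_spec(session_length = 30)
  tr1 <- run_closed_loop_session(user, dec, case, task, seed = 3)
  tr2 <- run_closed_loop_session(user, dec, case, task, seed = 3)
  expect_identical(tr1$steps, tr2$steps)
  expect_identical(tr1$events, tr2$events)

  # noise disabled, matched pair, constant intention: geometric approach via G
  y_const <- drop(case$A_motor) * 0.5
  xh <- decode_sequence(dec, matrix(rep(y_const, 50), 50, 6, byrow = TRUE),
                        xhat0 = 0)
  gain <- drop(dec$F %*% case$A_motor)
  x_inf <- gain * 0.5 / (1 - drop(dec$G))
  expect_true(all(diff(drop(xh)) > -1e-12))   # monotone approach
  expect_equal(drop(xh)[50], x_inf, tolerance = 1e-2)
})

test_that("frozen-user tracing error matches the analytic stationary MSE", {
  case <- build_signal_case(1)
  user <- simulated_user(case$A_motor, update_rule = "frozen")
  dec <- solve_sskf(case$encoder_motor, case$prior)
  task <- task_spec(kind = "tracing", session_length = 2000)  # 2e4 steps
  tr <- run_closed_loop_session(user, dec, case, task, seed = 8)
  err2 <- (tr$steps$xhat - tr$steps$x_int)^2
  mse_an <- mse_objective(case$A_motor, dec$F, dec$G, case$prior, case$C)
  expect_lt(abs(mean(err2) - mse_an), 3 * batch_se(err2))
})

test_that("user learning descends the objective and matches the decoder's optimum", {
  case <- build_signal_case(1)
  prior <- case$prior; Syr <- case$Sigma_y_cal
  lam <- 0.1
  opt <- canonicalize_solution(coordinate_descent(
    prior, case$C, config = optimizer_config(lambda = lam, n_restarts = 2,
                                             seed = 7),
    Sigma_y_ref = Syr))
  dec <- opt$decoder
  obj_of <- function(A) full_objective(A, dec$F, dec$G, prior, case$C,
                                       lambda = lam, Sigma_y_ref = Syr)$total
  # frozen user and zero learning rate are identities
  u0 <- simulated_user(case$A_motor, learning_rate = 0)
  expect_identical(user_learning_update(u0, dec, prior, case$C, lam,
                                        Sigma_y_ref = Syr)$A_user,
                   case$A_motor)
  # already-optimal user is unchanged
  u_star <- simulated_user(opt$A)
  u_star2 <- user_learning_update(u_star, dec, prior, case$C, lam,
                                  Sigma_y_ref = Syr, grad_tol = 1e-3)
  expect_identical(u_star2$A_user, opt$A)
  # learning is monotone and reaches the optimal encoder
  user <- simulated_user(case$A_motor)
  f_prev <- obj_of(user$A_user)
  for (i in 1:1000) {
    user <- user_learning_update(user, dec, prior, case$C, lam,
                                 Sigma_y_ref = Syr)
    f_now <- obj_of(user$A_user)
    expect_lte(f_now, f_prev + 1e-12)
    f_prev <- f_now
  }
  expect_gt(compare_encoders(user$A_user, opt$A), 0.95)
})

test_that("RLS encoder estimation equals batch least squares", {
  set.seed(71)
  A_true <- matrix(stats::rnorm(12), 6, 2)
  X <- matrix(stats::rnorm(400), 200, 2)
  # noiseless probe: exact recovery
  expect_equal(rls_motor_imitation_init(X, X %*% t(A_true)), A_true,
               tolerance = 1e-8)
  # noisy probe: matches the batch normal equations
  Y <- X %*% t(A_true) + 0.5 * matrix(stats::rnorm(1200), 200, 6)
  A_batch <- t(solve(crossprod(X), crossprod(X, Y)))
  expect_equal(rls_motor_imitation_init(X, Y), A_batch, tolerance = 1e-8)
  # degenerate probes are rejected
  expect_error(rls_motor_imitation_init(cbind(X[, 1], X[, 1]), Y), "rank")
  expect_error(rls_motor_imitation_init(X[1:3, ], Y[1:3, ]), "probe samples")
})

test_that("session regression recovers the user's encoder", {
  case <- build_signal_case(1)
  user <- simulated_user(case$A_motor, update_rule = "frozen")
  dec <- solve_sskf(case$encoder_motor, case$prior)
  # noise disabled: exact recovery from intention = target
  tr0 <- run_closed_loop_session(user, dec, case, task_spec(session_length = 30),
                                 seed = 2, noise = FALSE)
  expect_equal(estimate_encoder_regression(tr0), case$A_motor, tolerance = 1e-10)
  # with noise: consistent as the session grows
  tr <- run_closed_loop_session(user, dec, case, task_spec(session_length = 600),
                                seed = 4)
  A_hat <- estimate_encoder_regression(tr)
  expect_lt(max(abs(A_hat - case$A_motor)) / max(abs(case$A_motor)), 0.05)
  # shuffled target column: coefficients near zero
  tr_sh <- tr
  set.seed(5)
  tr_sh$steps$target <- sample(tr_sh$steps$target)
  expect_lt(max(abs(estimate_encoder_regression(tr_sh))), 0.1)
})

test_that("encoder comparison is sign-blind and near zero for unrelated encoders", {
  set.seed(72)
  A <- matrix(stats::rnorm(6), 6, 1)
  expect_equal(compare_encoders(A, A), 1.0)
  expect_equal(stats::cor(as.vector(A), as.vector(-A)), -1.0)  # raw correlation
  expect_equal(compare_encoders(A, -A), 1.0)                   # canonicalized
  rs <- replicate(200, compare_encoders(A, matrix(stats::rnorm(6), 6, 1)))
  expect_lt(stats::quantile(abs(rs), 0.5), 0.6)
  expect_error(compare_encoders(A, matrix(0, 6, 1)), "zero-variance")
})

test_that("pinball metrics match a hand-built fixture and survive a round trip", {
  tr <- fixture_trace(acq_times = c(30, 60), session_length = 60)
  m <- pinball_metrics(tr)
  expect_identical(m$targets_acquired, 2L)
  expect_equal(m$inter_acquisition_times, c(30, 30))
  expect_equal(m$targets_per_min, 2)
  expect_identical(m$misses, 0L)
  # no acquisitions: zero rate, misses counted
  tr2 <- fixture_trace(acq_times = numeric(0), miss_times = c(15, 30, 45),
                       session_length = 60)
  m2 <- pinball_metrics(tr2)
  expect_equal(m2$targets_per_time, 0)
  expect_identical(m2$misses, 3L)
  # wrong task kind
  tr$task$kind <- "tracing"
  expect_error(pinball_metrics(tr), "pinball")
  # metrics unchanged by serialization round trip
  tr <- fixture_trace(acq_times = c(30, 60), session_length = 60)
  prefix <- file.path(tempdir(), "fixture_trace")
  write_session_trace(tr, prefix, arm = "test")
  tr_back <- read_session_trace(prefix)
  expect_equal(pinball_metrics(tr_back)[c("targets_acquired", "misses")],
               m[c("targets_acquired", "misses")])
  expect_equal(pinball_metrics(tr_back)$inter_acquisition_times,
               m$inter_acquisition_times)
})

test_that("decoder comparison implements the one-sided unpaired t-test", {
  # identical samples: boundary p = 0.5, not significant
  same <- c(12, 15, 11, 14)
  r <- compare_decoders(same, same)
  expect_equal(r$p_value, 0.5, tolerance = 1e-12)
  expect_false(r$significant)
  # textbook pooled-variance computation as oracle
  x <- c(10, 11, 12); y <- c(20, 21, 19)
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- stats::pt(t_hand, df = 4, lower.tail = FALSE)
  r2 <- compare_decoders(x, y)
  expect_equal(r2$t, t_hand, tolerance = 1e-12)
  expect_equal(r2$p_value, p_hand, tolerance = 1e-12)
  r3 <- compare_decoders(y, x)   # motor faster: p < .05 in that direction
  expect_true(r3$significant)
  # swapping sides reverses the tail under equal variances
  expect_equal(r2$p_value, 1 - r3$p_value, tolerance = 1e-12)
  expect_error(compare_decoders(c(1), c(2, 3)), "at least 2")
})

test_that("cursor ACF matches AR(1) theory and white-noise bounds", {
  set.seed(73)
  x_ar <- as.numeric(stats::arima.sim(list(ar = 0.6), 1e5))
  a <- cursor_acf(x_ar, max_lag = 10)
  expect_equal(a[1], 1.0)
  expect_equal(a[2:11], 0.6^(1:10), tolerance = 0.03)
  x_wn <- stats::rnorm(1e4)
  expect_lt(max(abs(cursor_acf(x_wn, 10)[-1])), 3 / sqrt(1e4))
  expect_error(cursor_acf(rep(1, 100), 10), "variance")
  expect_error(cursor_acf(stats::rnorm(5), 10), "max_lag")
})
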