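# Shared fixtures: random model instances and independent oracles.

# random stable prior + encoder pair
random_instance <- function(n = NULL, k = NULL, radius_max = 0.9) {
  if (is.null(n)) n <- sample(1:3, 1)
  if (is.null(k)) k <- sample(1:6, 1)
  prior <- kinematic_prior(random_stable_matrix(n, stats::runif(1, 0.2, radius_max)),
                           random_spd_matrix(n), n)
  enc <- encoder(matrix(stats::rnorm(k * n), k, n), random_spd_matrix(k))
  list(prior = prior, enc = enc, n = n, k = k)
}

# central finite-difference gradient of the full objective in A (oracle)
fd_grad_objective <- function(A, F_gain, G, prior, C, lambda, penalty_kind,
                              Sigma_y_ref = NULL) {
  g <- A * 0
  h <- 1e-6 * (1 + sqrt(sum(A^2)))
  for (i in seq_along(A)) {
    Ap <- A; Ap[i] <- Ap[i] + h
    Am <- A; Am[i] <- Am[i] - h
    fp <- full_objective(Ap, F_gain, G, prior, C, lambda, penalty_kind,
                         Sigma_y_ref = Sigma_y_ref)$total
    fm <- full_objective(Am, F_gain, G, prior, C, lambda, penalty_kind,
                         Sigma_y_ref = Sigma_y_ref)$total
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}

# Monte-Carlo standard error of a mean over an autocorrelated series,
# by batch means
batch_se <- function(x, n_batches = 20) {
  T_len <- length(x)
  bsize <- floor(T_len / n_batches)
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bsize + 1):(b * bsize)]), 0)
  stats::sd(means) / sqrt(n_batches)
}

# minimal hand-built pinball trace for metric fixtures
fixture_trace <- function(acq_times, miss_times = numeric(0),
                          session_length = 60) {
  task <- task_spec(session_length = session_length)
  T_steps <- session_length * task$sample_rate
  steps <- data.frame(step = seq_len(T_steps),
                      time_s = seq_len(T_steps) / task$sample_rate,
                      target = 0.5, x_int = 0.5, y_1 = 0, xhat = 0,
                      in_halo = FALSE, event = "")
  for (tm in acq_times) steps$event[round(tm * task$sample_rate)] <- "acquire"
  for (tm in miss_times) steps$event[round(tm * task$sample_rate)] <- "miss"
  ev <- steps$event != ""
  structure(list(steps = steps,
                 events = data.frame(time_s = steps$time_s[ev],
                                     type = steps$event[ev]),
                 task = task, seed = 0, phase = "testing", case_id = 1,
                 A_user_final = matrix(1)),
            class = "session_trace")
}

# the shared end-to-end OPS comparison used by the closed-loop tests
# (computed once per test run)
ops_comparison_case1 <- local({
  cache <- NULL
  function(n_sessions = 20, seed = 101) {
    if (is.null(cache)) cache <<- run_ops_comparison(1, n_sessions = n_sessions,
                                                     seed = seed)
    cache
  }
})
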