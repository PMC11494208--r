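# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# canonical packaged studies at a fixed seed
study_severe <- function() cached("severe", function()
  suppressMessages(simulated_drift_study("severe", seed = 1)))
study_moderate <- function() cached("moderate", function()
  suppressMessages(simulated_drift_study("moderate", seed = 1)))
study_stationary <- function() cached("stationary", function()
  suppressMessages(simulated_drift_study("stationary", seed = 1)))

# small cheap closed-loop study for module-level tests
mini_study <- function(n_sessions = 2, C = 16, drift_rot = 0) {
  key <- sprintf("mini_%d_%d_%d", n_sessions, C, drift_rot)
  cached(key, function() {
    set.seed(42)
    pop <- population_spec(C = C)
    sched <- drift_schedule(
      session_day = seq(0L, by = 10L, length.out = n_sessions),
      pd_rotation_deg = seq(0, drift_rot, length.out = n_sessions))
    suppressMessages(generate_study(sched, pop = pop, n_blocks = 1,
                                    block_s = 150, seed = 42))
  })
}

# deterministic hand-built session: straight-line trials, constant
# decoded velocity per trial, white-noise features
toy_session <- function(n_trials = 4, bins_per_trial = 50, C = 3,
                        seed = 7, session_day = 0) {
  set.seed(seed)
  T_ <- n_trials * bins_per_trial
  targets <- matrix(c(0.4, 0, 0, 0.4, -0.4, 0, 0, -0.4), ncol = 2,
                    byrow = TRUE)
  cursor <- matrix(0, T_, 2)
  target <- matrix(0, T_, 2)
  vel <- matrix(0, T_, 2)
  trials <- data.frame()
  for (i in seq_len(n_trials)) {
    rows <- ((i - 1) * bins_per_trial + 1):(i * bins_per_trial)
    tg <- targets[(i - 1) %% nrow(targets) + 1, ]
    frac <- seq(0, 0.8, length.out = bins_per_trial)
    cursor[rows, ] <- outer(frac, tg)
    target[rows, ] <- matrix(tg, bins_per_trial, 2, byrow = TRUE)
    vel[rows, ] <- matrix(tg / sqrt(sum(tg^2)) * 0.3, bins_per_trial, 2,
                          byrow = TRUE)
    trials <- rbind(trials, data.frame(
      start_bin = rows[1], go_cue_bin = rows[1],
      end_bin = rows[length(rows)] + 1L,
      target_x = tg[1], target_y = tg[2], success = TRUE,
      packet_drop_frac = 0, outlier = FALSE))
  }
  binned_session(session_day = session_day,
                 features = matrix(rnorm(T_ * C), T_, C),
                 decoded_velocity = vel, cursor_pos = cursor,
                 target_pos = target, block_id = rep(1L, T_),
                 trials = trials)
}

# synthetic cosine-tuned sample set in the shape extract_tuning_samples
# produces: n_trials trials x bins_per_trial bins, one feature
make_tuning_samples <- function(md, pd_deg, n_trials = 40,
                                bins_per_trial = 50, noise_sd = 1,
                                seed = 1, b0 = 0) {
  set.seed(seed)
  theta_tr <- runif(n_trials, 0, 360)
  theta <- rep(theta_tr, each = bins_per_trial)
  y <- b0 + md * cos((theta - pd_deg) * pi / 180) +
    rnorm(length(theta), 0, noise_sd)
  structure(
    list(theta = theta,
         trial_id = rep(seq_len(n_trials), each = bins_per_trial),
         Y = matrix(y, ncol = 1), session_day = 0L,
         n_trials = n_trials),
    class = "tuning_samples")
}

random_gaussian_summary <- function(k, scale = 1) {
  A <- matrix(rnorm(k * k), k)
  S <- crossprod(A) / k + diag(0.2, k)
  structure(list(mean = rnorm(k, sd = scale), cov = S * scale,
                 n = Inf, k = k, ridge_applied = 0,
                 chol = chol(S * scale)),
            class = "gaussian_summary")
}
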