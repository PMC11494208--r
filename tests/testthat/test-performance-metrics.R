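# two-trial session with hand-set geometry for exact AE values
ae_fixture <- function(vel) {
  T_ <- nrow(vel)
  trials <- data.frame(start_bin = 1L, go_cue_bin = 1L, end_bin = T_ + 1L,
                       target_x = 0, target_y = 0.4, success = TRUE,
                       packet_drop_frac = 0, outlier = FALSE)
  binned_session(0, matrix(0, T_, 2), vel, matrix(0, T_, 2),
                 matrix(c(0, 0.4), T_, 2, byrow = TRUE),
                 rep(1L, T_), trials)
}

test_that("angle error hits the exact parallel/orthogonal/antiparallel values", {
  s <- ae_fixture(rbind(c(0, 1), c(1, 0), c(0, -1), c(-0.3, 0.3)))
  ae <- angle_error(s)$ae
  expect_equal(ae[1:3], c(0, 90, 180))
  expect_equal(ae[4], 45)
})

test_that("degenerate vectors and out-of-trial bins are masked", {
  s <- ae_fixture(rbind(c(0, 1), c(0, 0)))
  s$trials$end_bin <- 2L                        # bin 2 outside any trial
  trace <- angle_error(s)
  expect_identical(trace$valid, c(TRUE, FALSE))
  expect_true(is.na(trace$ae[2]))
})

test_that("angle error is invariant to gain and joint rotation", {
  set.seed(8)
  vel <- matrix(rnorm(20), ncol = 2)
  s <- ae_fixture(vel)
  base <- angle_error(s)$ae
  s_scaled <- s; s_scaled$decoded_velocity <- vel * 7.3
  expect_equal(angle_error(s_scaled)$ae, base)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s_rot <- s
  s_rot$decoded_velocity <- vel %*% t(R)
  d <- s$target_pos - s$cursor_pos
  s_rot$target_pos <- s$cursor_pos + d %*% t(R)
  expect_equal(angle_error(s_rot)$ae, base, tolerance = 1e-10)
})

test_that("windowed medians use the even-count convention and shared grid", {
  st <- mini_study()
  s <- st$sessions[[1]]
  trace <- angle_error(s)
  trace$ae[trace$valid] <- 30
  med <- windowed_median_ae(trace)
  expect_true(all(med$median_ae == 30, na.rm = TRUE))
  trace$ae[trace$valid] <- rep_len(c(0, 180), sum(trace$valid))
  med2 <- windowed_median_ae(trace)
  expect_true(all(med2$median_ae == 90, na.rm = TRUE))
  # identical grid to the divergence trace
  ref <- suppressMessages(mindful_reference(st$sessions,
                                            composition = "xhat",
                                            ae_threshold_deg = NULL))
  tr <- mindful_trace(ref, s)
  expect_identical(med$window_start_s, tr$window_start_s)
  expect_identical(med$window_end_s, tr$window_end_s)
})

test_that("windows short on valid bins emit missing values", {
  s <- mini_study()$sessions[[1]]
  trace <- angle_error(s)
  # invalidate a 50-s stretch: windows mostly inside it fall under 50%
  lo <- 4001L; hi <- 6500L
  trace$ae[lo:hi] <- NA_real_
  trace$valid[lo:hi] <- FALSE
  med <- windowed_median_ae(trace)
  gap <- med$window_start_s >= (lo - 1) * 0.02 &
    med$window_end_s <= hi * 0.02 + 10
  expect_true(any(is.na(med$median_ae[gap])))
  expect_true(all(med$n_valid[gap] <= 1500))
})

test_that("per-trial medians and their summary match closed forms", {
  s <- ae_fixture(rbind(c(0, 1), c(0, 1)))
  out <- per_trial_median_ae(s)
  expect_equal(out$trials$median_ae, 0)
  expect_equal(out$sd, NA_real_)

  # two constant-AE trials at 10 and 30 degrees
  vel <- rbind(matrix(rep(c(sin(10 * pi / 180), cos(10 * pi / 180)), 5),
                      ncol = 2, byrow = TRUE),
               matrix(rep(c(sin(30 * pi / 180), cos(30 * pi / 180)), 5),
                      ncol = 2, byrow = TRUE))
  s2 <- ae_fixture(vel)
  s2$trials <- rbind(s2$trials, s2$trials)
  s2$trials$start_bin <- c(1L, 6L)
  s2$trials$go_cue_bin <- c(1L, 6L)
  s2$trials$end_bin <- c(6L, 11L)
  out2 <- per_trial_median_ae(s2)
  expect_equal(out2$trials$median_ae, c(10, 30), tolerance = 1e-10)
  expect_equal(out2$mean, 20, tolerance = 1e-10)
  expect_equal(out2$sd, sd(c(10, 30)), tolerance = 1e-10)
})

test_that("correlation diagnostics behave on exact and null inputs", {
  set.seed(9)
  x <- runif(200)
  out <- score_performance_correlation(x, x)
  expect_equal(out$pearson_r, 1)
  expect_equal(out$spearman_rho, 1)
  out_neg <- score_performance_correlation(x, -x)
  expect_equal(out_neg$pearson_r, -1)
  expect_equal(out_neg$spearman_rho, -1)
  noise <- score_performance_correlation(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(noise$pearson_r), 0.05)
  expect_error(score_performance_correlation(1:2, 1:2), "3")
  # listwise NA dropping
  y <- x; y[1:50] <- NA
  expect_identical(score_performance_correlation(x, y)$n, 150L)
})

test_that("no-drift sessions show no early-late difference in trial AE", {
  st <- mini_study(n_sessions = 2)
  cmp <- suppressMessages(
    compare_day_groups(st$sessions, days_a = 0, days_b = 10))
  expect_gt(cmp$p_value, 0.05)
  expect_lt(abs(cmp$group_a$mean - cmp$group_b$mean), 10)
})
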