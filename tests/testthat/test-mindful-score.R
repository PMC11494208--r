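test_that("gaussian summaries match closed forms and stay unridged when healthy", {
  g <- gaussian_summary(rbind(c(0, 0), c(2, 0)))
  expect_equal(g$mean, c(1, 0))
  expect_equal(g$cov[1, 1], 2 + g$ridge_applied)
  expect_gt(g$ridge_applied, 0)                 # rank-1 sample needs ridge

  set.seed(10)
  mu <- c(1, -2, 0.5)
  A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3)
  X <- MASS::mvrnorm(1e5, mu, S)
  g2 <- gaussian_summary(X)
  expect_lt(norm(g2$cov - S, "F") / norm(S, "F"), 0.02)
  expect_lt(max(abs(g2$mean - mu)), 0.05)
  expect_identical(g2$ridge_applied, 0)

  X3 <- matrix(rnorm(3000 * 9), ncol = 9)       # one 60-s window worth
  expect_identical(gaussian_summary(X3)$ridge_applied, 0)
  expect_error(gaussian_summary(matrix(1, 1, 2)), "2 samples")
})

test_that("closed-form KLD matches hand values and is a true divergence", {
  p <- gaussian_summary(cbind(rnorm(100)))
  expect_lt(gaussian_kld(p, p), 1e-10)
  # k = 1, unit variances, unit mean shift -> 1/2
  P1 <- random_gaussian_summary(1)
  P1$mean <- 0; P1$cov <- matrix(1); P1$chol <- chol(P1$cov)
  P2 <- P1; P2$mean <- 1
  expect_equal(gaussian_kld(P1, P2), 0.5)
  set.seed(11)
  for (i in 1:20) {
    A <- random_gaussian_summary(3); B <- random_gaussian_summary(3)
    expect_gte(gaussian_kld(A, B), 0)
  }
})

test_that("alternate divergences satisfy their identities", {
  set.seed(12)
  A <- random_gaussian_summary(3); B <- random_gaussian_summary(3)
  for (kind in c("jeffreys", "bhattacharyya", "wasserstein2"))
    expect_lt(alt_divergence(A, A, kind), 1e-10)
  expect_equal(alt_divergence(A, B, "jeffreys"),
               gaussian_kld(A, B) + gaussian_kld(B, A))
  expect_equal(alt_divergence(A, B, "jeffreys"),
               alt_divergence(B, A, "jeffreys"))

  # scalar case against hand algebra
  s1 <- 1.3; s2 <- 0.6; m1 <- 0.2; m2 <- -1.1
  P1 <- random_gaussian_summary(1); P2 <- random_gaussian_summary(1)
  P1$mean <- m1; P1$cov <- matrix(s1); P1$chol <- chol(P1$cov)
  P2$mean <- m2; P2$cov <- matrix(s2); P2$chol <- chol(P2$cov)
  sbar <- (s1 + s2) / 2
  bh <- (m2 - m1)^2 / (8 * sbar) + 0.5 * log(sbar / sqrt(s1 * s2))
  expect_equal(alt_divergence(P1, P2, "bhattacharyya"), bh)
  w2 <- sqrt((m2 - m1)^2 + (sqrt(s1) - sqrt(s2))^2)
  expect_equal(alt_divergence(P1, P2, "wasserstein2"), w2)
})

test_that("KLD is invariant under a shared affine map of both samples", {
  set.seed(13)
  X <- matrix(rnorm(4000), ncol = 4)
  Y <- sweep(matrix(rnorm(4000), ncol = 4) %*% diag(c(1, 2, 1, 0.5)),
             2, c(0.3, 0, -0.2, 0.1), "+")
  base <- gaussian_kld(gaussian_summary(X), gaussian_summary(Y))
  for (i in 1:5) {
    m <- random_affine(4)
    Xa <- sweep(X %*% t(m$A), 2, m$b, "+")
    Ya <- sweep(Y %*% t(m$A), 2, m$b, "+")
    expect_lt(abs(gaussian_kld(gaussian_summary(Xa),
                               gaussian_summary(Ya)) - base), 1e-6)
  }
})

test_that("reference selection honours AE threshold, subset and sector", {
  st <- mini_study()
  sel_all <- select_reference_bins(st$sessions, ae_threshold_deg = NULL)
  sel_4 <- select_reference_bins(st$sessions, ae_threshold_deg = 4)
  expect_lt(sel_4$n_selected, sel_all$n_selected)
  expect_identical(sum(sel_all$masks[[2]]), 0L)   # only day 0 by default
  # selected fraction equals the empirical rate among eligible bins
  trace <- angle_error(st$sessions[[1]])
  eligible <- sel_all$masks[[1]]
  expect_equal(sum(sel_4$masks[[1]]) / sum(eligible),
               mean(trace$ae[eligible] < 4), tolerance = 1e-10)
  sel_up <- select_reference_bins(st$sessions, ae_threshold_deg = NULL,
                                  direction_sector = "up")
  expect_lt(sel_up$n_selected, sel_all$n_selected)
  d <- st$sessions[[1]]$target_pos - st$sessions[[1]]$cursor_pos
  ang <- atan2(d[, 2], d[, 1]) * 180 / pi
  chosen <- sel_up$masks[[1]]
  expect_true(all(abs(((ang[chosen] - 90 + 180) %% 360) - 180) <= 45))
  expect_error(select_reference_bins(st$sessions, ae_threshold_deg = 1e-9),
               "empty reference")
})

test_that("the trace grid steps by one second and flags starved windows", {
  st <- mini_study()
  ref <- suppressMessages(mindful_reference(st$sessions))
  tr <- mindful_trace(ref, st$sessions[[1]])
  steps <- diff(tr$window_start_s[tr$block == 1])
  expect_true(all(steps == 1))
  expect_true(all(tr$window_end_s - tr$window_start_s == 60))
  expect_true(all(tr$kld[!is.na(tr$kld)] >= 0))
  # a window overlapping an invalidated stretch is starved below k + 2
  expect_true(all(is.na(tr$kld[tr$n_bins < ref$gaussian$k + 2])))

  ref2 <- suppressMessages(mindful_reference(st$sessions,
                                             composition = "xhat",
                                             ae_threshold_deg = NULL))
  expect_error(
    {
      bad <- ref2; bad$gaussian$k <- 9L
      mindful_trace(bad, st$sessions[[1]])
    },
    "configuration")
})

test_that("a planted mean shift raises the trace by the quadratic term", {
  st <- mini_study()
  ref <- suppressMessages(mindful_reference(st$sessions,
                                            composition = "xhat",
                                            ae_threshold_deg = NULL))
  s <- st$sessions[[1]]
  base <- mindful_trace(ref, s)$kld
  delta <- 0.5 * sqrt(diag(ref$gaussian$cov))    # half an SD per dim
  s2 <- s
  s2$decoded_velocity <- sweep(s$decoded_velocity, 2, delta, "+")
  shifted <- mindful_trace(ref, s2)$kld
  lift <- mean(shifted - base, na.rm = TRUE)
  expect_gt(lift, 0.05)
  expect_lt(abs(lift - 0.25), 0.15)              # ~ delta' Sigma^-1 delta / 2
})

test_that("AE-binned divergence uses 45 intervals and a zero first bin", {
  st <- mini_study(n_sessions = 2, drift_rot = 0)
  ab <- suppressMessages(kld_by_ae_bins(st$sessions, n_components = 3))
  expect_identical(nrow(ab$table), 45L)
  expect_identical(ab$table$ae_lo[1], 0)
  expect_identical(ab$table$ae_hi[45], 180)
  expect_identical(ab$table$kld[1], 0)
  expect_true(all(ab$table$kld >= 0, na.rm = TRUE))
})

test_that("pairwise session divergence is asymmetric but level-matched for twins", {
  st <- mini_study(n_sessions = 2)
  ref <- suppressMessages(mindful_reference(st$sessions))
  M <- pairwise_session_mean_kld(st$sessions, ref)
  expect_identical(dim(M), c(2L, 2L))
  expect_false(isTRUE(all.equal(M[1, 2], M[2, 1])))
  # same generating distribution: between-level close to within-level
  expect_lt(M[1, 2], 3 * max(M[1, 1], M[2, 2]))
  expect_gt(M[1, 2], 0)
})

test_that("a drifted session sits farther from day 0 than day 0 from itself", {
  st <- mini_study(n_sessions = 2, drift_rot = 60)
  ref <- suppressMessages(mindful_reference(st$sessions))
  M <- pairwise_session_mean_kld(st$sessions, ref)
  expect_gt(M[1, 2], M[1, 1])
})
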