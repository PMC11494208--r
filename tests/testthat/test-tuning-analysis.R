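test_that("noiseless cosine fits are exact", {
  theta <- rep(seq(0, 315, by = 45), each = 10)
  f1 <- fit_cosine(theta, 0 + 1 * cos(theta * pi / 180))
  expect_equal(f1$md, 1, tolerance = 1e-10)
  expect_equal(f1$pd, 0, tolerance = 1e-8)
  expect_lt(f1$p_value, 1e-12)
  f2 <- fit_cosine(theta, 2 * sin(theta * pi / 180))
  expect_equal(f2$md, 2, tolerance = 1e-10)
  expect_equal(f2$pd, 90, tolerance = 1e-8)
  expect_equal(f2$b0, 0, tolerance = 1e-12)
  expect_error(fit_cosine(rep(10, 20), rnorm(20)), "distinct")
})

test_that("md/pd survive a rotation of the direction frame", {
  theta <- rep(seq(0, 315, by = 45), each = 5)
  y <- 1.5 * cos((theta - 70) * pi / 180)
  f <- fit_cosine(theta, y)
  f_rot <- fit_cosine((theta + 40) %% 360, y)
  expect_equal(f_rot$md, f$md, tolerance = 1e-10)
  expect_equal(f_rot$pd, (f$pd + 40) %% 360, tolerance = 1e-8)
})

test_that("planted tuning is recovered from noisy samples at 40 trials", {
  sm <- make_tuning_samples(md = 0.8, pd_deg = 130, n_trials = 40,
                            noise_sd = 1, seed = 21)
  f <- fit_cosine(sm, 1)
  expect_lt(abs(f$md - 0.8) / 0.8, 0.2)
  expect_lt(min(abs(f$pd - 130), 360 - abs(f$pd - 130)), 10)
  expect_true(f$significant)
})

test_that("tuning samples come from the post-go-cue window of clean trials", {
  s <- mini_study()$sessions[[1]]
  s$trials$outlier[2] <- TRUE
  sm <- suppressMessages(extract_tuning_samples(s))
  expect_false(any(sm$trial_id == 2))
  # every observation sits in [go + 8, go + 57] bins of its trial
  tr <- s$trials
  full <- tr$end_bin - tr$go_cue_bin >= 58
  for (i in which(full & !tr$outlier)[1:3])
    expect_identical(sum(sm$trial_id == i), 50L)
})

test_that("delta tuning wraps the circle and is zero on itself", {
  mk <- function(md, pd) list(md = md, pd = pd)
  expect_equal(delta_tuning(mk(1, 350), mk(1, 10)),
               list(delta_md = 0, abs_delta_pd = 20))
  expect_equal(delta_tuning(mk(1, 10), mk(1, 190))$abs_delta_pd, 180)
  expect_equal(delta_tuning(mk(0.8, 0), mk(1, 0))$delta_md, -0.2)
  f <- mk(1.2, 77)
  expect_equal(delta_tuning(f, f), list(delta_md = 0, abs_delta_pd = 0))
})

test_that("bootstrap flags a planted rotation but not identical sessions", {
  a <- make_tuning_samples(md = 1, pd_deg = 40, n_trials = 40, seed = 31)
  b <- make_tuning_samples(md = 1, pd_deg = 100, n_trials = 40, seed = 32)
  set.seed(5)
  hit <- bootstrap_delta_significance(a, b, B = 400)
  expect_true(hit$significant_pd)
  expect_lte(hit$ci_pd[1], hit$ci_pd[2])
  expect_lt(abs(hit$delta_pd - 60), 15)
  set.seed(6)
  null <- bootstrap_delta_significance(a, a, B = 400)
  expect_false(null$significant_pd)
  expect_false(null$significant_md)
  expect_true(null$ci_md[1] <= 0 && null$ci_md[2] >= 0)
})

test_that("tuning maps keep only significant features, in order", {
  fits <- data.frame(feature = 1:5, b0 = 0, b1 = 1:5 / 10, b2 = 0.1,
                     md = 1, pd = 0, f_stat = 1, p_value = 0.5,
                     n_obs = 100,
                     significant = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  attr(fits, "session_day") <- 3L
  map <- build_tuning_map(fits)
  expect_identical(dim(map$params), c(3L, 3L))
  expect_identical(map$feature_ids, c(1L, 3L, 4L))
  fits$significant <- TRUE
  expect_identical(dim(build_tuning_map(fits)$params), c(3L, 5L))
})

test_that("tuning similarity hits the exact anchors and shares features", {
  fits <- data.frame(feature = 1:4, b0 = rnorm(4), b1 = rnorm(4),
                     b2 = rnorm(4), md = 1, pd = 0, f_stat = 1,
                     p_value = 0.01, n_obs = 100, significant = TRUE)
  attr(fits, "session_day") <- 0L
  map <- build_tuning_map(fits)
  expect_equal(tuning_similarity(map, map), 1)
  flipped <- map
  flipped$params <- -map$params
  expect_equal(tuning_similarity(map, flipped), -1)
  one <- map; one$feature_ids <- 99L
  expect_true(is.na(tuning_similarity(map, one)))
})

test_that("feature ordering clusters planted drift profiles contiguously", {
  set.seed(41)
  S <- 6
  profile_a <- seq(0, 1, length.out = S)
  profile_b <- c(0, 0, 1, 1, 0, 0)
  dmd <- cbind(sapply(1:4, function(i) profile_a + rnorm(S, 0, 0.02)),
               sapply(1:4, function(i) profile_b + rnorm(S, 0, 0.02)))
  dpd <- dmd * 90
  ord <- cluster_feature_order(dmd, dpd)
  expect_setequal(ord, 1:8)
  groups <- rep(1:2, each = 4)[ord]
  expect_identical(sum(diff(groups) != 0), 1L)    # contiguous blocks
  expect_identical(as.integer(cluster_feature_order(dmd[, 1, drop = FALSE],
                                                    dpd[, 1, drop = FALSE])),
                   1L)
})

test_that("mean divergence against an exactly opposed similarity gives r = -1", {
  set.seed(42)
  M <- matrix(runif(25), 5)
  out <- correlate_kld_with_similarity(M, -M)
  expect_equal(out$pearson_r, -1)
  ind <- correlate_kld_with_similarity(M, matrix(runif(25), 5))
  expect_lt(abs(ind$pearson_r), 0.9)
  expect_error(correlate_kld_with_similarity(M[1:2, 1:2], -M[1:2, 1:2]),
               "3")
})
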