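# build a condition_average object directly: C channels, D directions,
# Tn time bins, shared time course plus rank-2 direction structure
synthetic_ca <- function(C = 12, D = 8, Tn = 20, dir_gain = 1,
                         seed = 51, day = 0L) {
  set.seed(seed)
  mean_tc <- matrix(rnorm(C), C) %*% matrix(sin(seq_len(Tn) / 3), 1)
  U <- qr.Q(qr(matrix(rnorm(C * 2), C)))
  dirs <- (0:(D - 1)) * 360 / D
  blocks <- lapply(dirs, function(th) {
    a <- dir_gain * c(cos(th * pi / 180), sin(th * pi / 180))
    mean_tc + U %*% (a %o% seq(0, 1, length.out = Tn))
  })
  structure(list(Ybar = do.call(cbind, blocks), directions = dirs,
                 n_time = Tn, n_trials = rep(1L, D), session_day = day),
            class = "condition_average")
}

test_that("gaussian smoothing preserves mass and constants", {
  k <- mindful:::gauss_kernel(2.5)
  expect_equal(sum(k), 1)
  const <- matrix(5, 40, 2)
  expect_equal(mindful:::smooth_gauss(const, 2.5), const)
})

test_that("single-trial sectors average to that trial's smoothed trace", {
  # three 60-bin trials aimed at 0, 45 and 90 degrees from the origin
  set.seed(52)
  T_ <- 180L
  dirs <- c(0, 45, 90)
  trials <- data.frame(
    start_bin = c(1L, 61L, 121L), go_cue_bin = c(1L, 61L, 121L),
    end_bin = c(61L, 121L, 181L),
    target_x = 0.4 * cos(dirs * pi / 180),
    target_y = 0.4 * sin(dirs * pi / 180),
    success = TRUE, packet_drop_frac = 0, outlier = FALSE)
  s <- binned_session(0, matrix(rnorm(T_ * 4), T_, 4),
                      matrix(0, T_, 2), matrix(0, T_, 2),
                      matrix(0, T_, 2), rep(1L, T_), trials)
  z <- matrix(rnorm(T_ * 4), T_, 4)
  ca <- suppressMessages(condition_average(s, zfeatures = z))
  expect_identical(ca$directions, dirs)
  expect_identical(ca$n_trials, rep(1L, 3))
  for (g in 1:3) {
    rows <- (trials$go_cue_bin[g] + 8L):(trials$go_cue_bin[g] + 57L)
    expected <- t(mindful:::smooth_gauss(z[rows, , drop = FALSE], 2.5))
    got <- ca$Ybar[, (g - 1) * 50 + 1:50]
    expect_equal(got, expected, ignore_attr = TRUE)
  }
})

test_that("rank-2 direction structure is reconstructed exactly", {
  ca <- synthetic_ca()
  model <- fit_direction_dpca(ca)
  Y <- ca$Ybar
  arr <- array(Y, dim = c(12, 20, 8))
  Ydir <- Y - matrix(apply(arr, c(1, 2), mean), 12, 160)
  recon <- model$F %*% (model$D %*% Y)
  expect_lt(norm(recon - Ydir, "F") / norm(Ydir, "F"), 1e-8)
  # energy splits orthogonally between mean and direction parts
  expect_equal(sum(Y^2), sum(Ydir^2) + sum((Y - Ydir)^2))
})

test_that("VAF anchors: in-image targets give 1, direction-free targets near 0", {
  ca <- synthetic_ca()
  model <- fit_direction_dpca(ca)
  in_image <- model$F %*% matrix(rnorm(2 * 160), 2)
  expect_equal(vaf(in_image, model), 1, tolerance = 1e-6)
  flat <- synthetic_ca(dir_gain = 0, seed = 52)
  expect_error(fit_direction_dpca(flat), "rank")
  expect_lt(abs(vaf(flat, model)), 0.3)
  expect_error(vaf(matrix(0, 12, 160), model), "zero-norm")
  # scale invariance
  expect_equal(vaf(ca, model), vaf(ca$Ybar * 7, model))
})

test_that("weaker direction structure scores lower VAF under the day-0 model", {
  ca0 <- synthetic_ca(dir_gain = 1, seed = 53)
  model <- fit_direction_dpca(ca0)
  gains <- c(1, 0.6, 0.3, 0.1)
  vafs <- sapply(gains, function(g) {
    ca <- synthetic_ca(dir_gain = g, seed = 53)
    vaf(ca, model)
  })
  expect_true(all(diff(vafs) < 0))
  expect_true(vafs[1] > 0 && vafs[1] <= 1)
})

test_that("vaf~kld correlation handles exact and degenerate input", {
  v <- c(0.5, 0.4, 0.3, 0.2)
  out <- correlate_vaf_with_mean_kld(v, 2 - 3 * v)
  expect_equal(out$pearson_r, -1)
  expect_error(correlate_vaf_with_mean_kld(rep(0.5, 4), 1:4),
               "degenerate")
  expect_error(correlate_vaf_with_mean_kld(v[1:2], v[1:2]), "3")
})
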