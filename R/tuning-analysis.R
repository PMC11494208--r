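# signed circular difference in degrees, mapped to (-180, 180]
wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Extract cosine-tuning samples from a session
#'
#' Collects, per feature, the z-scored activity from the reach-initiation
#' window of every non-outlier trial: the first second after the go cue,
#' offset by a 160 ms reaction time (50 bins at 20 ms). Every bin in the
#' window is one regression observation sharing the trial's movement
#' direction, taken as the angle of `target - cursor` at the go-cue bin
#' (for center-out this is the target direction; for random targets it
#' is the inferred intended direction). Trials shorter than the window
#' are truncated to the available bins.
#'
#' @param s A `binned_session` with outliers flagged.
#' @param zfeatures Optional precomputed [rolling_zscore()] output.
#' @param offset_s Reaction-time offset after the go cue (default
#'   0.160 s).
#' @param duration_s Window length (default 1 s).
#' @param ... Passed to [rolling_zscore()] if recomputed.
#' @return Object of class `tuning_samples`: `theta` (degrees per
#'   observation), `trial_id`, `Y` (observations x features),
#'   `session_day`, `n_trials`.
#' @export
extract_tuning_samples <- function(s, zfeatures = NULL, offset_s = 0.160,
                                   duration_s = 1, ...) {
  if (is.null(zfeatures)) zfeatures <- rolling_zscore(s, ...)
  off <- as.integer(round(offset_s / s$bin_width))
  dur <- as.integer(round(duration_s / s$bin_width))
  tr <- s$trials
  rows <- list(); theta <- list(); tid <- list()
  n_trunc <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$outlier[i]) next
    from <- tr$go_cue_bin[i] + off
    to <- min(tr$go_cue_bin[i] + off + dur - 1L, tr$end_bin[i] - 1L)
    if (to < from) next
    if (to - from + 1L < dur) n_trunc <- n_trunc + 1L
    d <- c(tr$target_x[i], tr$target_y[i]) -
      s$cursor_pos[tr$go_cue_bin[i], ]
    th <- (atan2(d[2], d[1]) * 180 / pi) %% 360
    idx <- from:to
    rows[[length(rows) + 1L]] <- idx
    theta[[length(theta) + 1L]] <- rep(th, length(idx))
    tid[[length(tid) + 1L]] <- rep(i, length(idx))
  }
  if (n_trunc) message(n_trunc, " trial(s) truncated to available bins")
  if (!length(rows)) stop("no qualifying trials for tuning extraction")
  idx <- unlist(rows)
  structure(
    list(theta = unlist(theta), trial_id = unlist(tid),
         Y = zfeatures[idx, , drop = FALSE],
         session_day = s$session_day,
         n_trials = length(rows)),
    class = "tuning_samples"
  )
}

#' Fit a cosine tuning curve to one feature
#'
#' Ordinary least squares for `y = b0 + b1 cos(theta) + b2 sin(theta)`.
#' Modulation depth is `md = sqrt(b1^2 + b2^2)`; preferred direction is
#' `pd = atan2(b2, b1)` in `[0, 360)` degrees. Tuning is significant if
#' the overall regression F-test (2 and n - 3 df) has p < 0.05. For
#' z-scored inputs the intercept `b0` is near zero.
#'
#' @param theta Direction per observation, degrees (or a
#'   `tuning_samples` object, with `y` naming the feature column).
#' @param y Response per observation.
#' @return List of class `tuning_fit`: `b0`, `b1`, `b2`, `md`, `pd`,
#'   `f_stat`, `p_value`, `n_obs`, `significant`.
#' @export
fit_cosine <- function(theta, y) {
  if (inherits(theta, "tuning_samples")) {
    samples <- theta
    y <- samples$Y[, y]
    theta <- samples$theta
  }
  n <- length(y)
  if (n < 6) stop("need at least 6 observations")
  if (length(unique(round(theta, 10))) < 3)
    stop("fit error: need at least 3 distinct directions")
  th <- theta * pi / 180
  X <- cbind(1, cos(th), sin(th))
  qr_ <- qr(X)
  if (qr_$rank < 3) stop("fit error: rank-deficient design")
  b <- qr.coef(qr_, y)
  fit <- drop(X %*% b)
  sse <- sum((y - fit)^2)
  ssr <- sum((fit - mean(y))^2)
  f <- (ssr / 2) / (sse / (n - 3))
  p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  md <- sqrt(b[2]^2 + b[3]^2)
  pd <- (atan2(b[3], b[2]) * 180 / pi) %% 360
  structure(
    list(b0 = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3]),
         md = unname(md), pd = unname(pd), f_stat = f, p_value = p,
         n_obs = n, significant = p < 0.05),
    class = "tuning_fit"
  )
}

#' Fit cosine tuning for every feature of a session
#'
#' @param samples A `tuning_samples` object.
#' @return Data frame with one row per feature: `feature`, `b0`, `b1`,
#'   `b2`, `md`, `pd`, `f_stat`, `p_value`, `n_obs`, `significant`.
#' @export
fit_session_tuning <- function(samples) {
  C <- ncol(samples$Y)
  rows <- lapply(seq_len(C), function(j) {
    f <- fit_cosine(samples$theta, samples$Y[, j])
    data.frame(feature = j, b0 = f$b0, b1 = f$b1, b2 = f$b2, md = f$md,
               pd = f$pd, f_stat = f$f_stat, p_value = f$p_value,
               n_obs = f$n_obs, significant = f$significant)
  })
  out <- do.call(rbind, rows)
  attr(out, "session_day") <- samples$session_day
  out
}

#' Session-to-session change in tuning parameters
#'
#' `delta_md = md - md_ref` and
#' `|delta_pd| = min(360 - |pd - pd_ref|, |pd - pd_ref|)`, the shorter
#' arc on the circle, in `[0, 180]`. The reference fit is conventionally
#' the first day on which the feature was significantly tuned.
#'
#' @param fit,ref `tuning_fit` objects (or anything with `md`/`pd`).
#' @return List with `delta_md` and `abs_delta_pd` (degrees).
#' @export
delta_tuning <- function(fit, ref) {
  dpd <- abs(fit$pd - ref$pd)
  list(delta_md = fit$md - ref$md,
       abs_delta_pd = min(360 - dpd, dpd))
}

# per-trial sufficient statistics for fast cosine refits:
# each trial contributes n_t * u u' to X'X and u * sum(y) to X'y,
# where u = (1, cos theta, sin theta) is shared by all its bins
trial_suffstats <- function(samples, feature) {
  y <- samples$Y[, feature]
  ids <- unique(samples$trial_id)
  stats_ <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- samples$trial_id == ids[i]
    th <- samples$theta[sel][1L] * pi / 180
    u <- c(1, cos(th), sin(th))
    stats_[[i]] <- list(xtx = sum(sel) * tcrossprod(u),
                        xty = u * sum(y[sel]),
                        n = sum(sel))
  }
  stats_
}

refit_from_stats <- function(stats_, draw) {
  xtx <- matrix(0, 3, 3); xty <- numeric(3)
  for (i in draw) {
    xtx <- xtx + stats_[[i]]$xtx
    xty <- xty + stats_[[i]]$xty
  }
  if (abs(det(xtx)) < 1e-10 * max(abs(xtx))^3) return(NULL)
  b <- solve(xtx, xty)
  c(md = sqrt(b[2]^2 + b[3]^2),
    pd = (atan2(b[3], b[2]) * 180 / pi) %% 360)
}

#' Bootstrap significance of a tuning change between two sessions
#'
#' Resamples trials (not bins, to respect within-trial correlation) with
#' replacement within each session, refits the cosine model, and forms B
#' paired differences of MD and of PD; PD differences are signed
#' circular differences mapped to (-180, 180] before the percentile
#' confidence interval. A change is significant when its CI excludes
#' zero. Rank-deficient resamples are redrawn (capped at 10 B draws).
#'
#' @param samples_a,samples_b `tuning_samples` for the two sessions.
#' @param feature Feature (column) index to test.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @return List: `ci_md`, `ci_pd` (each `c(lo, hi)`), `delta_md`,
#'   `delta_pd` (point estimates), `significant_md`, `significant_pd`,
#'   `significant_change` (either quantity), `B`.
#' @export
bootstrap_delta_significance <- function(samples_a, samples_b, feature = 1,
                                         B = 1000, level = 0.95) {
  sa <- trial_suffstats(samples_a, feature)
  sb <- trial_suffstats(samples_b, feature)
  na <- length(sa); nb <- length(sb)
  point_a <- refit_from_stats(sa, seq_len(na))
  point_b <- refit_from_stats(sb, seq_len(nb))
  if (is.null(point_a) || is.null(point_b))
    stop("fit error: rank-deficient design in full data")
  dmd <- numeric(B); dpd <- numeric(B)
  draws <- 0L; got <- 0L
  while (got < B) {
    draws <- draws + 1L
    if (draws > 10L * B)
      stop("fit error: too many rank-deficient bootstrap resamples")
    fa <- refit_from_stats(sa, sample.int(na, na, replace = TRUE))
    fb <- refit_from_stats(sb, sample.int(nb, nb, replace = TRUE))
    if (is.null(fa) || is.null(fb)) next
    got <- got + 1L
    dmd[got] <- fb[["md"]] - fa[["md"]]
    dpd[got] <- wrap_deg(fb[["pd"]] - fa[["pd"]])
  }
  alpha <- 1 - level
  ci_md <- unname(stats::quantile(dmd, c(alpha / 2, 1 - alpha / 2)))
  ci_pd <- unname(stats::quantile(dpd, c(alpha / 2, 1 - alpha / 2)))
  sig_md <- ci_md[1] > 0 || ci_md[2] < 0
  sig_pd <- ci_pd[1] > 0 || ci_pd[2] < 0
  list(ci_md = ci_md, ci_pd = ci_pd,
       delta_md = point_b[["md"]] - point_a[["md"]],
       delta_pd = wrap_deg(point_b[["pd"]] - point_a[["pd"]]),
       significant_md = sig_md, significant_pd = sig_pd,
       significant_change = sig_md || sig_pd, B = B)
}

#' Build a session's population tuning map
#'
#' A tuning map is the 3 x N matrix of fitted coefficients (b0, b1, b2)
#' of the N features significantly tuned that session, columns ordered
#' by feature index.
#'
#' @param fits Data frame from [fit_session_tuning()].
#' @return Object of class `tuning_map`: `params` (3 x N),
#'   `feature_ids`, `session_day`.
#' @export
build_tuning_map <- function(fits) {
  sig <- fits[fits$significant, , drop = FALSE]
  if (!nrow(sig)) message("no significantly tuned features this session")
  sig <- sig[order(sig$feature), , drop = FALSE]
  params <- rbind(b0 = sig$b0, b1 = sig$b1, b2 = sig$b2)
  structure(
    list(params = params, feature_ids = sig$feature,
         session_day = attr(fits, "session_day")),
    class = "tuning_map"
  )
}

#' Similarity between two tuning maps
#'
#' Pearson correlation between the two 3 x N parameter matrices
#' restricted to features significant on both days, flattened. `NA`
#' when fewer than 2 features are shared.
#'
#' @param map_i,map_j `tuning_map` objects.
#' @return Scalar correlation (or `NA`).
#' @export
tuning_similarity <- function(map_i, map_j) {
  shared <- intersect(map_i$feature_ids, map_j$feature_ids)
  if (length(shared) < 2) return(NA_real_)
  a <- map_i$params[, match(shared, map_i$feature_ids), drop = FALSE]
  b <- map_j$params[, match(shared, map_j$feature_ids), drop = FALSE]
  stats::cor(as.vector(a), as.vector(b))
}

#' Pairwise tuning-similarity matrix over sessions
#'
#' @param maps List of `tuning_map` objects (one per session, in day
#'   order).
#' @return S x S symmetric matrix with session days as dimnames;
#'   diagonal 1.
#' @export
tuning_similarity_matrix <- function(maps) {
  S <- length(maps)
  days <- vapply(maps, function(m)
    if (is.null(m$session_day)) NA_integer_ else m$session_day, integer(1))
  M <- matrix(NA_real_, S, S, dimnames = list(days, days))
  for (i in seq_len(S)) for (j in i:S) {
    v <- if (i == j) 1 else tuning_similarity(maps[[i]], maps[[j]])
    M[i, j] <- v; M[j, i] <- v
  }
  M
}

#' Order features by hierarchical clustering of their drift profiles
#'
#' Concatenates each feature's standardized across-session profile of
#' delta-MD and delta-PD, clusters features by Euclidean distance with
#' Ward linkage, and returns the dendrogram leaf order (a permutation
#' of the retained feature columns). Missing entries (sessions where a
#' feature was not significantly tuned) are imputed at the standardized
#' mean; all-missing features are excluded.
#'
#' @param delta_md,delta_pd S x F matrices (sessions x features).
#' @return Integer permutation of the retained feature columns, with
#'   attribute `"features"` naming the retained columns.
#' @export
cluster_feature_order <- function(delta_md, delta_pd) {
  delta_md <- as.matrix(delta_md); delta_pd <- as.matrix(delta_pd)
  stopifnot(identical(dim(delta_md), dim(delta_pd)))
  keep <- which(colSums(!is.na(delta_md)) > 0 |
                  colSums(!is.na(delta_pd)) > 0)
  if (length(keep) == 1L) {
    out <- 1L
    attr(out, "features") <- keep
    return(out)
  }
  std_cols <- function(M) {
    apply(M, 2, function(v) {
      mu <- mean(v, na.rm = TRUE)
      sd_ <- stats::sd(v, na.rm = TRUE)
      z <- if (is.finite(sd_) && sd_ > 0) (v - mu) / sd_ else v - mu
      z[is.na(z)] <- 0
      z
    })
  }
  prof <- rbind(std_cols(delta_md[, keep, drop = FALSE]),
                std_cols(delta_pd[, keep, drop = FALSE]))
  hc <- stats::hclust(stats::dist(t(prof)), method = "ward.D2")
  out <- hc$order
  attr(out, "features") <- keep
  out
}

#' Correlation between mean pairwise KLD and tuning-map similarity
#'
#' Pearson correlation over the upper-triangle session pairs of the two
#' matrices (both values present); a strong negative value says larger
#' distribution shift goes with less similar encoding.
#'
#' @param mean_kld S x S matrix from [pairwise_session_mean_kld()].
#' @param similarity S x S matrix from [tuning_similarity_matrix()].
#' @return List: `pearson_r`, `p_value`, `n_pairs`.
#' @export
correlate_kld_with_similarity <- function(mean_kld, similarity) {
  stopifnot(identical(dim(mean_kld), dim(similarity)))
  ut <- upper.tri(mean_kld)
  x <- mean_kld[ut]; y <- similarity[ut]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete session pairs")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = sum(ok))
}
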