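#' Instantaneous angle error of closed-loop cursor control
#'
#' Angle error (AE) at each bin is the absolute angle, in degrees,
#' between the inferred intended direction `d = target - cursor` and the
#' decoded velocity vector: 0 deg is perfect, 180 deg is opposite. Bins
#' outside any trial, or with a degenerate (near-zero) intended or
#' decoded vector, are masked invalid. AE is invariant to positive
#' rescaling of the decoded velocity and to rigid rotations applied
#' jointly to both vectors.
#'
#' @param s A `binned_session`.
#' @param exclude_outliers If `TRUE`, bins inside outlier-flagged trials
#'   are also masked invalid (default `FALSE`).
#' @param eps Norm below which a vector is treated as zero.
#' @return An object of class `ae_trace`: list with `ae` (degrees,
#'   length T, `NA` where invalid), `valid`, `session_day`, `block_id`,
#'   `bin_width`.
#' @export
angle_error <- function(s, exclude_outliers = FALSE, eps = 1e-12) {
  d <- s$target_pos - s$cursor_pos
  v <- s$decoded_velocity
  nd <- sqrt(rowSums(d * d))
  nv <- sqrt(rowSums(v * v))
  tr_idx <- trial_index(s)
  valid <- !is.na(tr_idx) & nd > eps & nv > eps
  if (exclude_outliers && nrow(s$trials)) {
    out_tr <- which(s$trials$outlier)
    if (length(out_tr))
      valid <- valid & !(!is.na(tr_idx) & tr_idx %in% out_tr)
  }
  cosang <- rowSums(d * v) / (nd * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  ae <- acos(cosang) * 180 / pi
  ae[!valid] <- NA_real_
  structure(
    list(ae = ae, valid = valid, session_day = s$session_day,
         block_id = s$block_id, bin_width = s$bin_width),
    class = "ae_trace"
  )
}

# Shared sliding-window grid: trailing windows anchored at each block
# start, right edge advancing in steps; windows never straddle blocks.
# Returns global start/end bins (inclusive) per window.
window_grid <- function(block_id, bin_width, window_s, step_s) {
  win <- as.integer(round(window_s / bin_width))
  step <- max(1L, as.integer(round(step_s / bin_width)))
  if (win < step) stop("'window_s' must be at least 'step_s'")
  out <- list()
  for (b in unique(block_id)) {
    rows <- which(block_id == b)
    n_blk <- length(rows)
    if (n_blk < win) next
    ends <- seq.int(win, n_blk, by = step)
    out[[length(out) + 1L]] <- data.frame(
      block = b,
      start_bin = rows[1L] + ends - win,
      end_bin = rows[1L] + ends - 1L
    )
  }
  if (!length(out))
    return(data.frame(block = integer(), start_bin = integer(),
                      end_bin = integer()))
  do.call(rbind, out)
}

#' Windowed median angle error
#'
#' Median AE over valid bins in each trailing sliding window (60 s by
#' default, stepped by 1 s), on the identical window grid used by
#' [mindful_trace()] so the two series can be correlated directly.
#' Windows with fewer than `min_frac` valid bins emit `NA`. The median
#' of an even count is the mean of the two central order statistics.
#'
#' @param trace An `ae_trace` from [angle_error()].
#' @param window_s,step_s Window length and step in seconds (defaults
#'   60 and 1).
#' @param min_frac Minimum fraction of valid bins per window (default
#'   0.5).
#' @return Data frame with one row per window: `session_day`, `block`,
#'   `window_start_s`, `window_end_s`, `median_ae`, `n_valid`.
#' @export
windowed_median_ae <- function(trace, window_s = 60, step_s = 1,
                               min_frac = 0.5) {
  grid <- window_grid(trace$block_id, trace$bin_width, window_s, step_s)
  win <- as.integer(round(window_s / trace$bin_width))
  med <- numeric(nrow(grid))
  n_valid <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    vals <- trace$ae[grid$start_bin[i]:grid$end_bin[i]]
    vals <- vals[!is.na(vals)]
    n_valid[i] <- length(vals)
    med[i] <- if (length(vals) >= min_frac * win) stats::median(vals) else NA_real_
  }
  data.frame(
    session_day = trace$session_day,
    block = grid$block,
    window_start_s = (grid$start_bin - 1L) * trace$bin_width,
    window_end_s = grid$end_bin * trace$bin_width,
    median_ae = med,
    n_valid = n_valid
  )
}

#' Per-trial median angle error
#'
#' Median of the valid AE bins within each trial span, plus the mean and
#' sample SD across trials — the summary used to compare early vs late
#' session groups. Trials with no valid bins are excluded.
#'
#' @param s A `binned_session`.
#' @param exclude_outliers Passed to [angle_error()].
#' @return List with `trials` (data frame: `trial`, `session_day`,
#'   `median_ae`, `n_valid`, `success`, `outlier`), `mean`, `sd`.
#' @export
per_trial_median_ae <- function(s, exclude_outliers = FALSE) {
  trace <- angle_error(s, exclude_outliers = exclude_outliers)
  tr <- s$trials
  med <- vapply(seq_len(nrow(tr)), function(i) {
    vals <- trace$ae[tr$start_bin[i]:(tr$end_bin[i] - 1L)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) stats::median(vals) else NA_real_
  }, numeric(1))
  n_valid <- vapply(seq_len(nrow(tr)), function(i) {
    sum(!is.na(trace$ae[tr$start_bin[i]:(tr$end_bin[i] - 1L)]))
  }, integer(1))
  keep <- !is.na(med)
  if (any(!keep))
    message(sum(!keep), " trial(s) with no valid AE bins excluded")
  out <- data.frame(trial = which(keep), session_day = s$session_day,
                    median_ae = med[keep], n_valid = n_valid[keep],
                    success = tr$success[keep], outlier = tr$outlier[keep])
  list(trials = out, mean = mean(out$median_ae),
       sd = stats::sd(out$median_ae))
}

#' Correlate a drift trace with windowed performance
#'
#' Pearson and Spearman correlations between a MINDFUL (KLD) series and
#' a windowed median-AE series sharing the same window grid; windows may
#' be pooled across sessions. Pairs with a missing value in either
#' series are dropped listwise.
#'
#' @param kld Numeric vector, or the data frame from [mindful_trace()]
#'   (column `kld` used).
#' @param med_ae Numeric vector of equal length, or the data frame from
#'   [windowed_median_ae()] (column `median_ae` used).
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
score_performance_correlation <- function(kld, med_ae) {
  if (is.data.frame(kld)) kld <- kld$kld
  if (is.data.frame(med_ae)) med_ae <- med_ae$median_ae
  if (length(kld) != length(med_ae))
    stop("series must share the window grid (equal length)")
  ok <- !is.na(kld) & !is.na(med_ae)
  x <- kld[ok]; y <- med_ae[ok]
  if (length(x) < 3) stop("need at least 3 complete window pairs")
  pe <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Compare per-trial AE between two day groups
#'
#' Two-sided Wilcoxon rank-sum test on pooled per-trial median AE from
#' two groups of sessions (e.g. early vs late days).
#'
#' @param sessions List of `binned_session` objects.
#' @param days_a,days_b Integer vectors of `session_day` values defining
#'   the two groups.
#' @param exclude_outliers Passed through to [per_trial_median_ae()].
#' @return List with group summaries (`mean`, `sd`, `n` each) and the
#'   `wilcox` htest object (`p_value` duplicated for convenience).
#' @export
compare_day_groups <- function(sessions, days_a, days_b,
                               exclude_outliers = FALSE) {
  pull <- function(days) {
    vals <- lapply(sessions, function(s) {
      if (s$session_day %in% days)
        per_trial_median_ae(s, exclude_outliers)$trials$median_ae
      else numeric(0)
    })
    unlist(vals)
  }
  a <- pull(days_a); b <- pull(days_b)
  if (!length(a) || !length(b))
    stop("one of the day groups selected no trials")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(group_a = list(mean = mean(a), sd = stats::sd(a), n = length(a)),
       group_b = list(mean = mean(b), sd = stats::sd(b), n = length(b)),
       wilcox = wt, p_value = wt$p.value)
}
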