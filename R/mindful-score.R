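#' Gaussian summary (mean, covariance) of a sample of derived features
#'
#' Computes the sample mean and unbiased (n - 1) covariance of an
#' n x k sample. If the covariance is ill-conditioned (condition number
#' above 1e8), singular, or the sample is too small for an invertible
#' estimate (n <= k), a diagonal ridge proportional to `trace(cov) / k`
#' is added, escalating by factors of 10 from 1e-8 until the matrix is
#' positive definite; the total added ridge is recorded. The upper
#' Cholesky factor is cached for reuse by divergence computations.
#'
#' @param samples n x k numeric matrix (n >= 2).
#' @param ridge Starting ridge multiplier (default 0: only applied when
#'   conditioning demands it).
#' @return Object of class `gaussian_summary`: `mean`, `cov`, `n`, `k`,
#'   `ridge_applied`, `chol` (upper triangular).
#' @export
gaussian_summary <- function(samples, ridge = 0) {
  samples <- as.matrix(samples)
  n <- nrow(samples); k <- ncol(samples)
  if (n < 2) stop("need at least 2 samples for a covariance estimate")
  mu <- colMeans(samples)
  S <- stats::cov(samples)
  S <- (S + t(S)) / 2
  scale <- sum(diag(S)) / k
  if (scale <= 0) scale <- 1
  applied <- 0
  if (ridge > 0) {
    applied <- ridge * scale
    S <- S + diag(applied, k)
  }
  needs_check <- n <= k || applied == 0
  R <- tryCatch(chol(S), error = function(e) NULL)
  bad_cond <- FALSE
  if (!is.null(R) && needs_check) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    bad_cond <- min(ev) <= 0 || max(ev) / min(ev) > 1e8
  }
  if (is.null(R) || bad_cond || n <= k) {
    lambda <- 1e-8
    repeat {
      add <- lambda * scale
      R <- tryCatch(chol(S + diag(add, k)), error = function(e) NULL)
      if (!is.null(R)) {
        ev <- eigen(S + diag(add, k), symmetric = TRUE,
                    only.values = TRUE)$values
        if (min(ev) > 0 && max(ev) / min(ev) <= 1e8) break
      }
      lambda <- lambda * 10
      if (lambda > 1e8) stop("conditioning error: covariance cannot be regularised")
    }
    S <- S + diag(add, k)
    applied <- applied + add
  }
  structure(
    list(mean = mu, cov = S, n = n, k = k,
         ridge_applied = applied, chol = R),
    class = "gaussian_summary"
  )
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("<gaussian_summary> k = %d, n = %d, ridge = %.3g\n",
              x$k, x$n, x$ridge_applied))
  invisible(x)
}

chol_of <- function(P, label) {
  if (!is.null(P$chol)) return(P$chol)
  tryCatch(chol(P$cov),
           error = function(e)
             stop("conditioning error: covariance of ", label,
                  " is not positive definite"))
}

#' Kullback-Leibler divergence between two Gaussian summaries
#'
#' Closed form for k-dimensional multivariate Gaussians:
#' \deqn{d_{KL}(P_1 \| P_2) = \tfrac12\big(\mathrm{tr}(\Sigma_2^{-1}\Sigma_1)
#'   + (\mu_2-\mu_1)^\top \Sigma_2^{-1} (\mu_2-\mu_1) - k
#'   + \ln(\det\Sigma_2 / \det\Sigma_1)\big)}
#' evaluated via Cholesky factors (triangular solves; log-determinants
#' from factor diagonals), never an explicit inverse or determinant.
#' Always non-negative; zero iff the summaries coincide. Note the
#' asymmetry: the second argument's covariance is the one inverted.
#'
#' @param P1,P2 `gaussian_summary` objects of equal dimension (P1 plays
#'   the reference role in the MINDFUL convention).
#' @return Non-negative scalar divergence (nats).
#' @export
gaussian_kld <- function(P1, P2) {
  k <- P1$k
  if (k != P2$k) stop("summaries have different dimensions")
  R1 <- chol_of(P1, "P1")
  R2 <- chol_of(P2, "P2")
  # tr(S2^-1 S1) with S1 = R1' R1: solve X = R2'^-1 R1', trace = ||X||_F^2
  X <- forwardsolve(t(R2), t(R1))
  tr <- sum(X * X)
  w <- forwardsolve(t(R2), P2$mean - P1$mean)
  quad <- sum(w * w)
  logdet <- 2 * (sum(log(diag(R2))) - sum(log(diag(R1))))
  max(0, 0.5 * (tr + quad - k + logdet))
}

#' Alternative closed-form Gaussian divergences
#'
#' Companions to [gaussian_kld()] on the same summaries:
#' `"jeffreys"` is the symmetrised KL, `d(P1||P2) + d(P2||P1)`;
#' `"bhattacharyya"` is
#' `(1/8) dm' S^-1 dm + (1/2) ln(det S / sqrt(det S1 det S2))` with
#' `S = (S1 + S2)/2`; `"wasserstein2"` is the 2-Wasserstein distance,
#' `sqrt(||dm||^2 + tr(S1 + S2 - 2 (S2^1/2 S1 S2^1/2)^1/2))`.
#' All are zero when the summaries coincide.
#'
#' @param P1,P2 `gaussian_summary` objects of equal dimension.
#' @param kind One of `"jeffreys"`, `"bhattacharyya"`, `"wasserstein2"`.
#' @return Non-negative scalar.
#' @export
alt_divergence <- function(P1, P2,
                           kind = c("jeffreys", "bhattacharyya",
                                    "wasserstein2")) {
  kind <- match.arg(kind)
  if (P1$k != P2$k) stop("summaries have different dimensions")
  dm <- P2$mean - P1$mean
  if (kind == "jeffreys")
    return(gaussian_kld(P1, P2) + gaussian_kld(P2, P1))
  if (kind == "bhattacharyya") {
    Sbar <- (P1$cov + P2$cov) / 2
    Rb <- tryCatch(chol(Sbar), error = function(e)
      stop("conditioning error: average covariance not positive definite"))
    w <- forwardsolve(t(Rb), dm)
    R1 <- chol_of(P1, "P1"); R2 <- chol_of(P2, "P2")
    logdet_bar <- 2 * sum(log(diag(Rb)))
    logdet_1 <- 2 * sum(log(diag(R1)))
    logdet_2 <- 2 * sum(log(diag(R2)))
    return(max(0, sum(w * w) / 8 +
                 0.5 * (logdet_bar - 0.5 * (logdet_1 + logdet_2))))
  }
  # wasserstein2: cross term via symmetric square roots
  S2h <- sym_sqrt(P2$cov)
  cross <- sym_sqrt(S2h %*% P1$cov %*% S2h)
  val <- sum(dm * dm) + sum(diag(P1$cov)) + sum(diag(P2$cov)) -
    2 * sum(diag(cross))
  sqrt(max(0, val))
}

sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

sector_axes <- c(right = 0, up = 90, left = 180, down = 270)

#' Select reference time bins across sessions
#'
#' Returns per-session logical masks of bins eligible for the reference
#' distribution: bins inside trials with valid angle error, restricted
#' (optionally) to AE below a threshold, to an intended-direction sector
#' (within 45 degrees of the up/down/left/right axis), and to a subset
#' of session days. Warm-up bins (first 30 s of a block) and the first
#' bin of each block (no lag) are always excluded, matching the validity
#' mask of [build_derived_features()].
#'
#' @param sessions List of `binned_session` objects.
#' @param ae_threshold_deg AE inclusion threshold in degrees (default
#'   4); `NULL` disables AE subsampling (reference from any control
#'   quality, as when reference data comes from free personal use).
#' @param session_days Days to draw reference bins from; default the
#'   first session's day.
#' @param direction_sector Optional sector name (`"up"`, `"down"`,
#'   `"left"`, `"right"`).
#' @param exclude_outliers Drop bins inside outlier-flagged trials.
#' @param min_s Warm-up exclusion in seconds (default 30).
#' @return List with `masks` (per-session logical vectors), `n_selected`
#'   and a `counts` data frame of per-filter survivor counts. Errors if
#'   the selection is empty.
#' @export
select_reference_bins <- function(sessions, ae_threshold_deg = 4,
                                  session_days = NULL,
                                  direction_sector = NULL,
                                  exclude_outliers = FALSE, min_s = 30) {
  if (is.null(session_days))
    session_days <- sessions[[1L]]$session_day
  n_subset <- 0L; n_ae_valid <- 0L; n_below <- 0L; n_sector <- 0L
  masks <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    T_ <- n_bins(s)
    if (!(s$session_day %in% session_days)) {
      masks[[i]] <- logical(T_)
      next
    }
    trace <- angle_error(s, exclude_outliers = exclude_outliers)
    min_bins <- max(2L, as.integer(round(min_s / s$bin_width)))
    t_rel <- stats::ave(seq_len(T_), s$block_id, FUN = seq_along)
    m <- trace$valid & t_rel > min_bins & duplicated(s$block_id)
    n_subset <- n_subset + T_
    n_ae_valid <- n_ae_valid + sum(m)
    if (!is.null(ae_threshold_deg))
      m <- m & !is.na(trace$ae) & trace$ae < ae_threshold_deg
    n_below <- n_below + sum(m)
    if (!is.null(direction_sector)) {
      axis <- sector_axes[[match.arg(direction_sector,
                                     names(sector_axes))]]
      d <- s$target_pos - s$cursor_pos
      ang <- atan2(d[, 2], d[, 1]) * 180 / pi
      dd <- abs(((ang - axis + 180) %% 360) - 180)
      m <- m & dd <= 45
    }
    n_sector <- n_sector + sum(m)
    masks[[i]] <- m
  }
  counts <- data.frame(
    filter = c("in_subset", "valid_ae", "below_threshold", "in_sector"),
    n = c(n_subset, n_ae_valid, n_below, n_sector))
  if (n_sector == 0L)
    stop("empty reference selection; survivors per filter: ",
         paste(sprintf("%s=%d", counts$filter, counts$n), collapse = ", "))
  list(masks = masks, n_selected = n_sector, counts = counts)
}

#' Build a MINDFUL reference model
#'
#' Assembles everything the score needs from the epoch of known good
#' control: the selected reference bins (see [select_reference_bins()]),
#' the PCA basis fitted on those bins' z-scored features (when the
#' composition includes `"pc"`; the PCA-reference data is the reference
#' data), and the Gaussian summary of the reference derived features.
#'
#' @inheritParams select_reference_bins
#' @param composition Derived-feature tags, see
#'   [build_derived_features()].
#' @param n_components Number of principal components M (default 5).
#' @param window_s_z,var_floor Rolling z-score parameters, see
#'   [rolling_zscore()].
#' @return Object of class `mindful_reference`: `gaussian`,
#'   `pca_basis` (or `NULL`), `composition`, `masks`, `selection_rule`,
#'   `zscore` (parameter list).
#' @export
mindful_reference <- function(sessions,
                              composition = c("pc", "xhat", "xhat_lag"),
                              n_components = 5, ae_threshold_deg = 4,
                              session_days = NULL, direction_sector = NULL,
                              exclude_outliers = FALSE, window_s_z = 180,
                              min_s = 30, var_floor = 1e-6) {
  sel <- select_reference_bins(sessions, ae_threshold_deg, session_days,
                               direction_sector, exclude_outliers, min_s)
  zargs <- list(window_s = window_s_z, min_s = min_s, var_floor = var_floor)
  use_pc <- "pc" %in% composition

  zf <- vector("list", length(sessions))
  basis <- NULL
  if (use_pc) {
    pool <- list()
    for (i in seq_along(sessions)) {
      if (!any(sel$masks[[i]])) next
      zf[[i]] <- rolling_zscore(sessions[[i]], window_s = window_s_z,
                                min_s = min_s, var_floor = var_floor)
      pool[[length(pool) + 1L]] <- zf[[i]][sel$masks[[i]], , drop = FALSE]
    }
    basis <- fit_reference_pca(do.call(rbind, pool), M = n_components,
                               fitted_on = "reference bins")
  }

  rows <- list()
  for (i in seq_along(sessions)) {
    if (!any(sel$masks[[i]])) next
    df <- build_derived_features(sessions[[i]], basis, composition,
                                 zfeatures = zf[[i]],
                                 window_s = window_s_z, min_s = min_s,
                                 var_floor = var_floor)
    m <- sel$masks[[i]] & df$valid
    rows[[length(rows) + 1L]] <- df$values[m, , drop = FALSE]
  }
  samples <- do.call(rbind, rows)
  structure(
    list(gaussian = gaussian_summary(samples),
         pca_basis = basis,
         composition = composition,
         masks = sel$masks,
         selection_rule = list(ae_threshold_deg = ae_threshold_deg,
                               session_days = session_days,
                               direction_sector = direction_sector,
                               exclude_outliers = exclude_outliers),
         zscore = zargs),
    class = "mindful_reference"
  )
}

#' @export
print.mindful_reference <- function(x, ...) {
  cat(sprintf("<mindful_reference> k = %d from %d bins [%s]\n",
              x$gaussian$k, x$gaussian$n,
              paste(x$composition, collapse = "+")))
  invisible(x)
}

# derived features for one session under a reference's configuration
derive_for_reference <- function(s, ref) {
  z <- ref$zscore
  build_derived_features(s, ref$pca_basis, ref$composition,
                         window_s = z$window_s, min_s = z$min_s,
                         var_floor = z$var_floor)
}

outlier_bin_mask <- function(s) {
  m <- logical(n_bins(s))
  tr <- s$trials
  for (i in which(tr$outlier))
    m[tr$start_bin[i]:(tr$end_bin[i] - 1L)] <- TRUE
  m
}

#' The MINDFUL trace: sliding-window divergence from reference
#'
#' For each trailing 60-s window (stepped by 1 s, anchored at block
#' starts, never straddling blocks) the derived features of the window's
#' valid bins are summarised as a Gaussian and compared with the
#' reference summary by closed-form KL divergence. The default direction
#' puts the reference first (`d_KL(ref || window)`, so the window
#' covariance is inverted); the asymmetry is material when window
#' covariances shrink, hence the explicit switch. Windows with fewer
#' than k + 2 valid bins emit `NA`.
#'
#' @param ref A `mindful_reference`.
#' @param sessions List of `binned_session` objects to score.
#' @param window_s,step_s Window length and step in seconds (defaults
#'   60 and 1), on the same grid as [windowed_median_ae()].
#' @param direction `"ref_vs_window"` (default) or `"window_vs_ref"`.
#' @param exclude_outliers Drop bins inside outlier trials from windows.
#' @return Data frame of class `mindful_trace`: `session_day`, `block`,
#'   `window_start_s`, `window_end_s`, `kld`, `n_bins`.
#' @export
mindful_trace <- function(ref, sessions, window_s = 60, step_s = 1,
                          direction = c("ref_vs_window", "window_vs_ref"),
                          exclude_outliers = FALSE) {
  direction <- match.arg(direction)
  if (inherits(sessions, "binned_session")) sessions <- list(sessions)
  k <- ref$gaussian$k
  out <- list()
  for (s in sessions) {
    df <- derive_for_reference(s, ref)
    if (df$k != k)
      stop("configuration error: derived dimension ", df$k,
           " does not match reference k = ", k)
    valid <- df$valid
    if (exclude_outliers) valid <- valid & !outlier_bin_mask(s)
    grid <- window_grid(s$block_id, s$bin_width, window_s, step_s)
    kld <- rep(NA_real_, nrow(grid))
    nb <- integer(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      rows <- grid$start_bin[i]:grid$end_bin[i]
      rows <- rows[valid[rows]]
      nb[i] <- length(rows)
      if (nb[i] < k + 2) next
      W <- gaussian_summary(df$values[rows, , drop = FALSE])
      kld[i] <- if (direction == "ref_vs_window")
        gaussian_kld(ref$gaussian, W) else gaussian_kld(W, ref$gaussian)
    }
    out[[length(out) + 1L]] <- data.frame(
      session_day = s$session_day, block = grid$block,
      window_start_s = (grid$start_bin - 1L) * s$bin_width,
      window_end_s = grid$end_bin * s$bin_width,
      kld = kld, n_bins = nb)
  }
  res <- do.call(rbind, out)
  class(res) <- c("mindful_trace", "data.frame")
  res
}

#' KL divergence grouped by angle-error interval
#'
#' Pools valid bins across sessions, groups them by instantaneous AE
#' into 4-degree intervals `[0,4), [4,8), ..., [176,180]` (45 intervals
#' at the default width), and computes the KLD between the low-AE
#' reference (all pooled bins with AE below one interval width — also
#' the PCA-reference data) and each interval's distribution of top-M PC
#' features. The first interval coincides with the reference, so its
#' divergence is exactly zero. Returns the per-interval table and the
#' Pearson correlation of KLD against interval midpoints, the linearity
#' diagnostic relating distribution shift to performance.
#'
#' @param sessions List of `binned_session` objects.
#' @param bin_width_deg AE interval width in degrees (default 4).
#' @param n_components Number of PCs M for the derived features
#'   (default 5).
#' @param exclude_outliers Drop bins inside outlier trials.
#' @param min_s,window_s_z,var_floor Rolling z-score parameters.
#' @return List: `table` (data frame `ae_lo`, `ae_hi`, `ae_mid`, `kld`,
#'   `n_bins`; empty intervals are `NA` and excluded from the fit),
#'   `pearson_r`, `pearson_p`, `n_reference`.
#' @export
kld_by_ae_bins <- function(sessions, bin_width_deg = 4, n_components = 5,
                           exclude_outliers = FALSE, window_s_z = 180,
                           min_s = 30, var_floor = 1e-6) {
  ae_all <- list(); z_sel <- list()
  for (s in sessions) {
    trace <- angle_error(s, exclude_outliers = exclude_outliers)
    z <- rolling_zscore(s, window_s = window_s_z, min_s = min_s,
                        var_floor = var_floor)
    keep <- trace$valid & attr(z, "valid")
    ae_all[[length(ae_all) + 1L]] <- trace$ae[keep]
    z_sel[[length(z_sel) + 1L]] <- z[keep, , drop = FALSE]
  }
  ae <- unlist(ae_all)
  zpool <- do.call(rbind, z_sel)
  is_ref <- ae < bin_width_deg
  if (sum(is_ref) < n_components + 2)
    stop("too few reference bins with AE < ", bin_width_deg, " deg")
  basis <- fit_reference_pca(zpool[is_ref, , drop = FALSE],
                             M = n_components, fitted_on = "low-AE bins")
  pcs <- project_pca(basis, zpool)
  k <- ncol(pcs)
  P_ref <- gaussian_summary(pcs[is_ref, , drop = FALSE])

  n_int <- as.integer(ceiling(180 / bin_width_deg))
  lo <- (seq_len(n_int) - 1L) * bin_width_deg
  hi <- pmin(lo + bin_width_deg, 180)
  kld <- rep(NA_real_, n_int)
  nb <- integer(n_int)
  for (i in seq_len(n_int)) {
    inb <- if (i == n_int) ae >= lo[i] & ae <= hi[i] else
      ae >= lo[i] & ae < hi[i]
    nb[i] <- sum(inb)
    if (nb[i] < k + 2) next
    if (i == 1L && identical(which(inb), which(is_ref)))
      kld[i] <- 0
    else
      kld[i] <- gaussian_kld(P_ref, gaussian_summary(pcs[inb, , drop = FALSE]))
  }
  tab <- data.frame(ae_lo = lo, ae_hi = hi, ae_mid = (lo + hi) / 2,
                    kld = kld, n_bins = nb)
  ok <- !is.na(kld)
  if (sum(ok) < 3) stop("fewer than 3 non-empty AE intervals")
  ct <- stats::cor.test(tab$ae_mid[ok], kld[ok], method = "pearson")
  list(table = tab, pearson_r = unname(ct$estimate),
       pearson_p = ct$p.value, n_reference = sum(is_ref))
}

#' Mean pairwise KL divergence between sessions
#'
#' Summarises the distribution shift between every pair of sessions:
#' each session is cut into trailing windows (60 s, stepped 10 s by
#' default; outlier-trial bins excluded), each window summarised as a
#' Gaussian of the reference-derived features, and entry (i, j) is the
#' mean of `d_KL(window of i || window of j)` over all window pairs.
#' The diagonal averages over distinct window pairs within the session
#' and measures within-session variability. The matrix is generally
#' asymmetric; use `(A + t(A)) / 2` for a symmetric view.
#'
#' @param sessions List of `binned_session` objects.
#' @param ref A `mindful_reference` (supplies the PCA basis, feature
#'   composition and z-score configuration).
#' @param window_s,step_s Window length and step in seconds (defaults
#'   60 and 10).
#' @param exclude_outliers Drop outlier-trial bins (default `TRUE`).
#' @return S x S numeric matrix with session days as dimnames and
#'   attribute `"n_windows"`; sessions with no complete window get `NA`
#'   rows/columns.
#' @export
pairwise_session_mean_kld <- function(sessions, ref, window_s = 60,
                                      step_s = 10,
                                      exclude_outliers = TRUE) {
  k <- ref$gaussian$k
  summaries <- vector("list", length(sessions))
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    df <- derive_for_reference(s, ref)
    valid <- df$valid
    if (exclude_outliers) valid <- valid & !outlier_bin_mask(s)
    grid <- window_grid(s$block_id, s$bin_width, window_s, step_s)
    ws <- list()
    for (i in seq_len(nrow(grid))) {
      rows <- grid$start_bin[i]:grid$end_bin[i]
      rows <- rows[valid[rows]]
      if (length(rows) < k + 2) next
      ws[[length(ws) + 1L]] <- gaussian_summary(df$values[rows, , drop = FALSE])
    }
    summaries[[si]] <- ws
  }
  S <- length(sessions)
  days <- vapply(sessions, function(s) s$session_day, integer(1))
  M <- matrix(NA_real_, S, S, dimnames = list(days, days))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    wi <- summaries[[i]]; wj <- summaries[[j]]
    if (!length(wi) || !length(wj)) next
    if (i == j && length(wi) < 2) next
    tot <- 0; cnt <- 0L
    for (a in seq_along(wi)) for (b in seq_along(wj)) {
      if (i == j && a == b) next
      tot <- tot + gaussian_kld(wi[[a]], wj[[b]])
      cnt <- cnt + 1L
    }
    M[i, j] <- tot / cnt
  }
  attr(M, "n_windows") <- vapply(summaries, length, integer(1))
  M
}
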