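# discrete Gaussian kernel (sd in bins), truncated at 4 sd, mass 1
gauss_kernel <- function(sd_bins) {
  h <- max(1L, as.integer(ceiling(4 * sd_bins)))
  k <- exp(-0.5 * ((-h):h / sd_bins)^2)
  k / sum(k)
}

# smooth columns of a (time x channels) matrix, renormalising the kernel
# at the edges so constants are preserved
smooth_gauss <- function(X, sd_bins) {
  k <- gauss_kernel(sd_bins)
  h <- (length(k) - 1L) %/% 2L
  Tn <- nrow(X)
  out <- matrix(0, Tn, ncol(X))
  for (t in seq_len(Tn)) {
    lo <- max(1L, t - h); hi <- min(Tn, t + h)
    w <- k[(lo - t + h + 1L):(hi - t + h + 1L)]
    w <- w / sum(w)
    out[t, ] <- w %*% X[lo:hi, , drop = FALSE]
  }
  out
}

#' Direction-conditioned trial-averaged population activity
#'
#' Builds the condition-averaged matrix the latent analysis consumes:
#' for each of `n_directions` movement-direction sectors (45-degree
#' sectors centred on 0, 45, ..., 315 degrees), the z-scored feature
#' trajectories over the reach-initiation window (go cue + 160 ms, 1 s,
#' i.e. 50 bins) of non-outlier trials are Gaussian-smoothed in time
#' (sd 50 ms) and averaged over trials. Direction blocks are
#' concatenated along time, giving a channels x (directions * 50)
#' matrix. Random-target trials are discretised into the sectors by
#' their intended direction at the go cue. Trials shorter than the
#' window, and empty sectors, are dropped (logged).
#'
#' @param s A `binned_session`.
#' @param zfeatures Optional precomputed [rolling_zscore()] output.
#' @param n_directions Number of direction sectors (default 8).
#' @param smoothing_sd Gaussian smoothing SD in seconds (default 0.050).
#' @param offset_s,duration_s Window definition (defaults 0.160 s and
#'   1 s), matching the tuning extraction.
#' @param ... Passed to [rolling_zscore()] if recomputed.
#' @return Object of class `condition_average`: `Ybar`
#'   (C x (D_present * n_time)), `directions` (sector centres present,
#'   degrees), `n_time`, `n_trials` (per present sector),
#'   `session_day`.
#' @export
condition_average <- function(s, zfeatures = NULL, n_directions = 8,
                              smoothing_sd = 0.050, offset_s = 0.160,
                              duration_s = 1, ...) {
  if (is.null(zfeatures)) zfeatures <- rolling_zscore(s, ...)
  off <- as.integer(round(offset_s / s$bin_width))
  dur <- as.integer(round(duration_s / s$bin_width))
  sd_bins <- smoothing_sd / s$bin_width
  width <- 360 / n_directions
  centres <- (seq_len(n_directions) - 1L) * width
  tr <- s$trials
  C <- ncol(s$features)
  acc <- lapply(seq_len(n_directions), function(i) NULL)
  cnt <- integer(n_directions)
  for (i in seq_len(nrow(tr))) {
    if (tr$outlier[i]) next
    from <- tr$go_cue_bin[i] + off
    to <- from + dur - 1L
    if (to > tr$end_bin[i] - 1L) next         # window incomplete
    d <- c(tr$target_x[i], tr$target_y[i]) - s$cursor_pos[tr$go_cue_bin[i], ]
    th <- (atan2(d[2], d[1]) * 180 / pi) %% 360
    sector <- (floor((th + width / 2) / width) %% n_directions) + 1L
    traj <- smooth_gauss(zfeatures[from:to, , drop = FALSE], sd_bins)
    acc[[sector]] <- if (is.null(acc[[sector]])) traj else acc[[sector]] + traj
    cnt[sector] <- cnt[sector] + 1L
  }
  present <- which(cnt > 0)
  if (!length(present)) stop("no complete trials for condition averaging")
  if (length(present) < n_directions)
    message(n_directions - length(present), " empty direction sector(s) dropped")
  blocks <- lapply(present, function(g) t(acc[[g]] / cnt[g]))  # C x Tn
  structure(
    list(Ybar = do.call(cbind, blocks),
         directions = centres[present], n_time = dur,
         n_trials = cnt[present], session_day = s$session_day),
    class = "condition_average"
  )
}

ybar_matrix <- function(x) {
  if (inherits(x, "condition_average")) x$Ybar else as.matrix(x)
}

#' Fit rank-2 direction components on day-0 activity
#'
#' Demixes the condition-averaged activity into a direction-independent
#' time course (the mean over directions, broadcast across direction
#' blocks) and the direction-dependent residual, then finds the rank-2
#' encoder F (C x 2) and decoder D (2 x C) that best reconstruct the
#' direction-dependent part from the full condition average: the
#' analytic reduced-rank regression solution (unregularised), i.e. the
#' least-squares map projected onto the top-2 principal subspace of its
#' fitted values. The decomposition is orthogonal, so
#' `||Ybar||^2 = ||Ymean||^2 + ||Ydir||^2`.
#'
#' @param ca_day0 A `condition_average` from the reference (day 0)
#'   session, with at least 2 directions present.
#' @return Object of class `latent_model`: `F` (C x 2), `D` (2 x C),
#'   `fitted_day`, `n_time`, `directions`, `smoothing_sd` absent fields
#'   carried from the input.
#' @export
fit_direction_dpca <- function(ca_day0) {
  if (!inherits(ca_day0, "condition_average"))
    stop("expected a condition_average object")
  Y <- ca_day0$Ybar
  Dn <- length(ca_day0$directions)
  if (Dn < 2) stop("need at least 2 directions present")
  Tn <- ca_day0$n_time
  C <- nrow(Y)
  arr <- array(Y, dim = c(C, Tn, Dn))
  Ymean <- apply(arr, c(1, 2), mean)
  Ydir <- Y - matrix(Ymean, C, Tn * Dn)      # broadcast over direction blocks
  if (sum(svd(Ydir, nu = 0, nv = 0)$d > 1e-12 * max(1, norm(Ydir, "F"))) < 2)
    stop("direction marginalisation has rank < 2")
  # minimum-norm least-squares map Ydir ~ B Y via SVD pseudo-inverse
  sv <- svd(Y)
  pos <- sv$d > max(sv$d) * 1e-10
  B <- Ydir %*% sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  fitted <- B %*% Y
  U <- svd(fitted, nu = 2, nv = 0)$u          # top-2 principal subspace
  structure(
    list(F = U, D = t(U) %*% B, fitted_day = ca_day0$session_day,
         n_time = Tn, directions = ca_day0$directions),
    class = "latent_model"
  )
}

#' Variance accounted for by the day-0 direction components
#'
#' `R^2 = (||Ybar||^2 - ||Ybar - F D Ybar||^2) / ||Ybar||^2` with
#' Frobenius norms, where `Ybar` is the condition average of a target
#' session and F, D stay fixed from the reference day. Values near the
#' day-0 level indicate a preserved direction subspace; values falling
#' toward 0 (or below) indicate latent drift. Invariant to global
#' rescaling of `Ybar`.
#'
#' @param ca A `condition_average` (or bare C x (D*Tn) matrix)
#'   dimension-compatible with the model.
#' @param model A `latent_model`.
#' @return Scalar in (-Inf, 1].
#' @export
vaf <- function(ca, model) {
  Y <- ybar_matrix(ca)
  if (nrow(Y) != nrow(model$F))
    stop("dimension mismatch: target has ", nrow(Y),
         " channels, model expects ", nrow(model$F))
  tot <- sum(Y * Y)
  if (tot == 0) stop("zero-norm condition average")
  resid <- Y - model$F %*% (model$D %*% Y)
  (tot - sum(resid * resid)) / tot
}

#' Correlate per-session VAF with mean KLD from day 0
#'
#' @param vaf_per_session Numeric vector of [vaf()] values, one per
#'   session in day order.
#' @param mean_kld_day0_row Matching vector of mean KLD between day 0
#'   and each session (a row of [pairwise_session_mean_kld()]).
#' @return List: `pearson_r`, `p_value`, `n`. Errors on fewer than 3
#'   complete pairs or a constant series (correlation undefined).
#' @export
correlate_vaf_with_mean_kld <- function(vaf_per_session,
                                        mean_kld_day0_row) {
  ok <- !is.na(vaf_per_session) & !is.na(mean_kld_day0_row)
  x <- vaf_per_session[ok]; y <- mean_kld_day0_row[ok]
  if (length(x) < 3) stop("need at least 3 sessions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: correlation undefined for a constant series")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(x))
}
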