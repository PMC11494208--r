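#' Causal rolling z-score of binned neural features
#'
#' Standardises each channel with the mean and (sample) variance of a
#' trailing window ending at, and including, the current bin — the same
#' adaptive normalisation applied during online decoding. Statistics
#' restart at block boundaries. For the first `window_s` seconds of a
#' block the window expands from the block start; bins up to and including
#' `min_s` seconds into a block are marked invalid (attribute `"valid"`)
#' and are excluded downstream from reference and comparison windows.
#'
#' @param features T x C numeric matrix of binned features, or a
#'   `binned_session` (in which case `block_id`/`bin_width` are taken
#'   from it).
#' @param bin_width Bin width in seconds (ignored when `features` is a
#'   session).
#' @param block_id Optional integer block labels, length T; default one
#'   block.
#' @param window_s Trailing window length in seconds (default 180, the
#'   3-minute online rule).
#' @param min_s Minimum warm-up before a bin is considered valid
#'   (default 30 s).
#' @param var_floor Variance clamp in squared feature units (default
#'   1e-6); silent or constant channels produce zeros rather than
#'   blow-ups.
#' @return T x C matrix of z-scored features with logical attribute
#'   `"valid"` (length T).
#' @export
rolling_zscore <- function(features, bin_width = 0.020, block_id = NULL,
                           window_s = 180, min_s = 30, var_floor = 1e-6) {
  if (inherits(features, "binned_session")) {
    s <- features
    features <- s$features
    bin_width <- s$bin_width
    block_id <- s$block_id
  }
  features <- as.matrix(features)
  T_ <- nrow(features)
  if (is.null(block_id)) block_id <- rep(1L, T_)
  stopifnot(length(block_id) == T_)
  if (window_s < 10 * bin_width)
    stop("'window_s' must be at least 10 bins long")
  win <- max(2L, as.integer(round(window_s / bin_width)))
  min_bins <- max(2L, as.integer(round(min_s / bin_width)))

  out <- matrix(0, T_, ncol(features), dimnames = dimnames(features))
  valid <- logical(T_)
  clamped <- logical(ncol(features))
  for (b in unique(block_id)) {
    rows <- which(block_id == b)
    x <- features[rows, , drop = FALSE]
    n_blk <- length(rows)
    cs <- apply(x, 2, cumsum)
    cs2 <- apply(x * x, 2, cumsum)
    cs <- rbind(0, cs)                       # prepend zero row: cs[t+1] = sum(1..t)
    cs2 <- rbind(0, cs2)
    t_rel <- seq_len(n_blk)
    n <- pmin(t_rel, win)
    lo <- t_rel - n                          # index into padded cumsum
    mu <- (cs[t_rel + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / n
    ss <- (cs2[t_rel + 1L, , drop = FALSE] - cs2[lo + 1L, , drop = FALSE])
    v <- (ss - n * mu * mu) / pmax(n - 1L, 1L)
    v[n < 2L, ] <- 0
    v <- pmax(v, 0)                          # guard cancellation
    low <- v < var_floor
    # warm-up bins always start clamped; only report post-warm-up clamps
    clamped <- clamped | apply(low & (t_rel > min_bins), 2, any)
    v[low] <- var_floor
    out[rows, ] <- (x - mu) / sqrt(v)
    valid[rows] <- t_rel > min_bins
  }
  if (any(clamped))
    message("rolling_zscore: variance clamped at floor for ",
            sum(clamped), " channel(s)")
  attr(out, "valid") <- valid
  out
}

#' Fit a PCA basis on reference z-scored features
#'
#' Returns the top-M principal components of the sample covariance of
#' the (centred) reference bins. Rows of `loadings` are orthonormal and
#' ordered by descending eigenvalue; the sign of each component is fixed
#' so its largest-magnitude entry is positive.
#'
#' @param zfeatures N x C matrix of z-scored reference bins.
#' @param M Number of components to keep (default 5).
#' @param fitted_on Optional label recording the reference bin set.
#' @return An object of class `pca_basis` with fields `center` (C),
#'   `loadings` (M x C), `var_explained` (length M), `M`, `fitted_on`.
#' @export
fit_reference_pca <- function(zfeatures, M = 5, fitted_on = NULL) {
  zfeatures <- as.matrix(zfeatures)
  C <- ncol(zfeatures)
  if (M > C)
    stop("dimension error: M = ", M, " exceeds channel count ", C)
  center <- colMeans(zfeatures)
  xc <- sweep(zfeatures, 2, center)
  sv <- svd(xc, nu = 0, nv = min(C, nrow(xc)))
  ev <- sv$d^2 / (nrow(zfeatures) - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (M > rank)
    stop("dimension error: M = ", M, " exceeds data rank ", rank)
  loadings <- t(sv$v[, seq_len(M), drop = FALSE])
  for (i in seq_len(M)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  structure(
    list(center = center, loadings = loadings,
         var_explained = ev[seq_len(M)], M = M,
         fitted_on = fitted_on),
    class = "pca_basis"
  )
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d components over %d channels\n",
              x$M, length(x$center)))
  invisible(x)
}

#' Project z-scored features onto a fitted PCA basis
#'
#' @param basis A `pca_basis`.
#' @param zfeatures T x C matrix (C must match the basis).
#' @return T x M matrix `(zfeatures - center) %*% t(loadings)`.
#' @export
project_pca <- function(basis, zfeatures) {
  zfeatures <- as.matrix(zfeatures)
  if (ncol(zfeatures) != length(basis$center))
    stop("dimension mismatch: data has ", ncol(zfeatures),
         " channels, basis expects ", length(basis$center))
  sweep(zfeatures, 2, basis$center) %*% t(basis$loadings)
}

#' Build the derived feature matrix the MINDFUL score compares
#'
#' Concatenates, in the declared order, any of three column blocks:
#' `"pc"` — the top-M PCA projections of the causally z-scored channel
#' features; `"xhat"` — the decoder's 2-D velocity output; `"xhat_lag"`
#' — the decoder output one bin (20 ms) earlier. The default
#' `c("pc", "xhat", "xhat_lag")` with M = 5 gives the 9-dimensional
#' feature set; `"xhat"` alone gives k = 2 and `c("xhat", "xhat_lag")`
#' gives k = 4.
#'
#' The first bin of each block has no lag and is marked invalid, as are
#' z-score warm-up bins; the validity mask is carried in `$valid` and
#' respected by all window statistics.
#'
#' @param s A `binned_session`.
#' @param basis A `pca_basis`, required when `"pc"` is in
#'   `composition`.
#' @param composition Character vector of tags from
#'   `c("pc", "xhat", "xhat_lag")`, in output order.
#' @param zfeatures Optional precomputed output of [rolling_zscore()]
#'   for `s` (recomputed if missing and needed).
#' @param ... Passed to [rolling_zscore()] when it is recomputed.
#' @return An object of class `derived_features`: list with `values`
#'   (T x k), `k`, `composition`, `valid` (logical T), `session_day`,
#'   `block_id`, `bin_width`.
#' @export
build_derived_features <- function(s, basis = NULL,
                                   composition = c("pc", "xhat", "xhat_lag"),
                                   zfeatures = NULL, ...) {
  if (!length(composition))
    stop("configuration error: empty feature composition")
  composition <- match.arg(composition, c("pc", "xhat", "xhat_lag"),
                           several.ok = TRUE)
  if (anyDuplicated(composition))
    stop("configuration error: duplicated composition tags")

  blocks <- list()
  valid <- rep(TRUE, n_bins(s))
  first_of_block <- !duplicated(s$block_id)
  for (tag in composition) {
    if (tag == "pc") {
      if (is.null(basis))
        stop("configuration error: composition includes 'pc' but no basis given")
      if (is.null(zfeatures))
        zfeatures <- rolling_zscore(s, ...)
      blk <- project_pca(basis, zfeatures)
      colnames(blk) <- sprintf("pc%d", seq_len(ncol(blk)))
      blocks[[tag]] <- blk
    } else if (tag == "xhat") {
      blk <- s$decoded_velocity
      colnames(blk) <- c("xhat_x", "xhat_y")
      blocks[[tag]] <- blk
    } else { # xhat_lag
      lag <- rbind(c(0, 0), s$decoded_velocity[-n_bins(s), , drop = FALSE])
      colnames(lag) <- c("xlag_x", "xlag_y")
      blocks[[tag]] <- lag
      valid <- valid & !first_of_block
    }
  }
  # warm-up mask applies whenever z-scoring is in play; recompute it from
  # block structure for velocity-only compositions so window semantics match
  if (!is.null(zfeatures)) {
    valid <- valid & attr(zfeatures, "valid")
  } else {
    zs_args <- list(...)
    min_s <- if (!is.null(zs_args$min_s)) zs_args$min_s else 30
    min_bins <- max(2L, as.integer(round(min_s / s$bin_width)))
    t_rel <- stats::ave(seq_len(n_bins(s)), s$block_id, FUN = seq_along)
    valid <- valid & t_rel > min_bins
  }

  values <- do.call(cbind, blocks)
  structure(
    list(values = values, k = ncol(values), composition = composition,
         valid = valid, session_day = s$session_day,
         block_id = s$block_id, bin_width = s$bin_width),
    class = "derived_features"
  )
}

#' @export
print.derived_features <- function(x, ...) {
  cat(sprintf("<derived_features> %d bins x k = %d [%s], %d valid\n",
              nrow(x$values), x$k, paste(x$composition, collapse = "+"),
              sum(x$valid)))
  invisible(x)
}
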