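#' Construct a binned iBCI recording session
#'
#' A `binned_session` holds one recording session of closed-loop cursor
#' control, resampled into non-overlapping time bins (20 ms by default):
#' a bins-by-channels neural feature matrix (threshold-crossing counts or
#' spike-band power), the decoded 2-D velocity emitted by the online
#' decoder, cursor and active-target positions per bin, block labels, and
#' a trial table.
#'
#' Bin indices are 1-based. Trials are half-open spans `[start_bin,
#' end_bin)` so `end_bin` may be `T + 1`; spans must be disjoint, ordered,
#' and lie within the session. Coordinates are screen units with the
#' origin at screen centre and y pointing up.
#'
#' @param session_day Integer day count since the day the decoder was
#'   first deployed (day 0).
#' @param features Numeric matrix, T bins x C channels.
#' @param decoded_velocity Numeric matrix, T x 2: decoder output
#'   (screen units / s) per bin.
#' @param cursor_pos,target_pos Numeric matrices, T x 2.
#' @param block_id Integer vector of length T, non-decreasing; a block is
#'   a contiguous run of task recording (normalisation and analysis
#'   windows restart at block boundaries).
#' @param trials Data frame with columns `start_bin`, `go_cue_bin`,
#'   `end_bin`, `target_x`, `target_y`, `success`, `packet_drop_frac`,
#'   `outlier`. May have zero rows.
#' @param bin_width Bin width in seconds (default 0.020).
#'
#' @return An object of class `binned_session`.
#' @seealso [read_session()], [write_session()], [flag_outlier_trials()],
#'   [simulate_session()]
#' @export
binned_session <- function(session_day, features, decoded_velocity,
                           cursor_pos, target_pos, block_id, trials,
                           bin_width = 0.020) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  s <- structure(
    list(
      session_day = as.integer(session_day),
      bin_width = as.numeric(bin_width),
      features = features,
      decoded_velocity = as_xy_matrix(decoded_velocity, "decoded_velocity"),
      cursor_pos = as_xy_matrix(cursor_pos, "cursor_pos"),
      target_pos = as_xy_matrix(target_pos, "target_pos"),
      block_id = as.integer(block_id),
      trials = as_trial_table(trials)
    ),
    class = "binned_session"
  )
  validate_binned_session(s)
  s
}

as_xy_matrix <- function(x, name) {
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop(sprintf("'%s' must have 2 columns, got %d", name, ncol(x)))
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y")
  x
}

trial_columns <- c("start_bin", "go_cue_bin", "end_bin", "target_x",
                   "target_y", "success", "packet_drop_frac", "outlier")

as_trial_table <- function(trials) {
  trials <- as.data.frame(trials)
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  trials <- trials[trial_columns]
  for (col in c("start_bin", "go_cue_bin", "end_bin"))
    trials[[col]] <- as.integer(trials[[col]])
  for (col in c("target_x", "target_y", "packet_drop_frac"))
    trials[[col]] <- as.numeric(trials[[col]])
  trials$success <- as.logical(trials$success)
  trials$outlier <- as.logical(trials$outlier)
  rownames(trials) <- NULL
  trials
}

#' Validate a binned_session against its invariants
#'
#' Checks array-length agreement, bin width, block monotonicity, and the
#' trial-span invariants (ordering, disjointness, containment,
#' `start_bin <= go_cue_bin < end_bin`, `packet_drop_frac` in \[0, 1\]).
#' Called by [binned_session()] and [read_session()].
#'
#' @param s A `binned_session`.
#' @return `s`, invisibly; errors describe the offending field.
#' @export
validate_binned_session <- function(s) {
  T_ <- nrow(s$features)
  for (fld in c("decoded_velocity", "cursor_pos", "target_pos")) {
    if (nrow(s[[fld]]) != T_)
      stop(sprintf("integrity error: '%s' has %d rows but 'features' has %d",
                   fld, nrow(s[[fld]]), T_))
  }
  if (length(s$block_id) != T_)
    stop(sprintf("integrity error: 'block_id' has length %d but 'features' has %d rows",
                 length(s$block_id), T_))
  if (!is.finite(s$bin_width) || s$bin_width <= 0)
    stop("format error: 'bin_width' must be a positive number")
  if (T_ > 1 && any(diff(s$block_id) < 0))
    stop("integrity error: 'block_id' must be non-decreasing")
  tr <- s$trials
  if (nrow(tr)) {
    if (any(tr$start_bin > tr$go_cue_bin) || any(tr$go_cue_bin >= tr$end_bin))
      stop("integrity error: trials must satisfy start_bin <= go_cue_bin < end_bin")
    if (any(tr$start_bin < 1L) || any(tr$end_bin > T_ + 1L))
      stop("integrity error: trial spans must lie within [1, T]")
    if (nrow(tr) > 1 && any(tr$start_bin[-1] < tr$end_bin[-nrow(tr)]))
      stop("integrity error: trial spans must be ordered and disjoint")
    if (any(tr$packet_drop_frac < 0 | tr$packet_drop_frac > 1))
      stop("integrity error: packet_drop_frac must lie in [0, 1]")
  }
  invisible(s)
}

#' @export
print.binned_session <- function(x, ...) {
  T_ <- nrow(x$features)
  cat(sprintf(
    "<binned_session> day %d: %d bins x %d channels (%.0f ms bins, %.1f s)\n",
    x$session_day, T_, ncol(x$features), 1000 * x$bin_width,
    T_ * x$bin_width))
  cat(sprintf("  blocks: %d | trials: %d (%d outlier)\n",
              length(unique(x$block_id)), nrow(x$trials),
              sum(x$trials$outlier)))
  invisible(x)
}

#' Number of bins in a session
#' @param s A `binned_session`.
#' @return Integer bin count T.
#' @export
n_bins <- function(s) nrow(s$features)

#' Per-bin trial membership
#'
#' @param s A `binned_session`.
#' @return Integer vector of length T: the trial-table row whose span
#'   contains each bin, or `NA` for bins outside every trial.
#' @export
trial_index <- function(s) {
  idx <- rep(NA_integer_, n_bins(s))
  tr <- s$trials
  for (i in seq_len(nrow(tr)))
    idx[tr$start_bin[i]:(tr$end_bin[i] - 1L)] <- i
  idx
}

#' Write a session to a directory
#'
#' Serialises a `binned_session` into a small directory layout intended
#' to be diffable and readable across languages: `meta.json`
#' (session-level scalars), a columnar bin table (`bins.parquet`, or
#' `bins.csv` when `format = "csv"`), and `trials.csv`. Numeric values
#' round-trip at full 64-bit precision in either format.
#'
#' @param s A valid `binned_session`.
#' @param path Directory to create/overwrite.
#' @param format `"parquet"` (default) or `"csv"` for the bin table.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path, format = c("parquet", "csv")) {
  format <- match.arg(format)
  validate_binned_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("I/O error: cannot create session directory ", path)

  meta <- list(session_day = s$session_day, bin_width = s$bin_width,
               n_channels = ncol(s$features), schema = "mindful-session-v1")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  C <- ncol(s$features)
  feat_names <- sprintf("feat_%03d", seq_len(C) - 1L)
  bins <- data.frame(
    bin_index = seq_len(n_bins(s)),
    block_id = s$block_id,
    s$features,
    vx_hat = s$decoded_velocity[, 1], vy_hat = s$decoded_velocity[, 2],
    cursor_x = s$cursor_pos[, 1], cursor_y = s$cursor_pos[, 2],
    target_x = s$target_pos[, 1], target_y = s$target_pos[, 2]
  )
  names(bins)[2L + seq_len(C)] <- feat_names
  if (format == "parquet") {
    arrow::write_parquet(bins, file.path(path, "bins.parquet"))
  } else {
    write_csv_full(bins, file.path(path, "bins.csv"))
  }
  write_csv_full(s$trials, file.path(path, "trials.csv"))
  invisible(path)
}

# full-precision CSV (doubles via 17 significant digits)
write_csv_full <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
}

#' Read a session directory
#'
#' Inverse of [write_session()]; accepts either `bins.parquet` or
#' `bins.csv`. The returned session is validated against all invariants.
#'
#' @param path Session directory.
#' @return A `binned_session`.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop("format error: missing meta.json in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (fld in c("session_day", "bin_width"))
    if (is.null(meta[[fld]]))
      stop("format error: meta.json lacks field '", fld, "'")

  pq <- file.path(path, "bins.parquet")
  cs <- file.path(path, "bins.csv")
  if (file.exists(pq)) {
    bins <- as.data.frame(arrow::read_parquet(pq))
  } else if (file.exists(cs)) {
    bins <- utils::read.csv(cs)
  } else {
    stop("format error: no bins.parquet or bins.csv in ", path)
  }
  needed <- c("bin_index", "block_id", "vx_hat", "vy_hat",
              "cursor_x", "cursor_y", "target_x", "target_y")
  missing <- setdiff(needed, names(bins))
  if (length(missing))
    stop("format error: bin table missing column(s): ",
         paste(missing, collapse = ", "))
  feat_cols <- grep("^feat_[0-9]+$", names(bins), value = TRUE)
  if (!length(feat_cols))
    stop("format error: bin table has no feat_### columns")
  feat_cols <- feat_cols[order(as.integer(sub("feat_", "", feat_cols)))]

  trials_file <- file.path(path, "trials.csv")
  if (!file.exists(trials_file))
    stop("format error: missing trials.csv in ", path)
  trials <- utils::read.csv(trials_file)
  if (nrow(trials) == 0)
    trials <- empty_trial_table()

  binned_session(
    session_day = meta$session_day,
    features = as.matrix(bins[feat_cols]),
    decoded_velocity = cbind(bins$vx_hat, bins$vy_hat),
    cursor_pos = cbind(bins$cursor_x, bins$cursor_y),
    target_pos = cbind(bins$target_x, bins$target_y),
    block_id = bins$block_id,
    trials = trials,
    bin_width = meta$bin_width
  )
}

empty_trial_table <- function() {
  data.frame(start_bin = integer(), go_cue_bin = integer(),
             end_bin = integer(), target_x = numeric(),
             target_y = numeric(), success = logical(),
             packet_drop_frac = numeric(), outlier = logical())
}

#' Flag outlier trials
#'
#' A trial is an outlier if it lost more than `drop_thresh` of its
#' wireless data packets, or if any bin inside the trial carries a
#' feature value more than `amp_sd` standard deviations above that
#' channel's mean. Channel means/SDs are computed over the whole session
#' excluding bins inside trials already flagged by the packet-drop rule;
#' zero-variance channels are skipped in the amplitude test.
#'
#' The operation is idempotent, and lowering `amp_sd` flags a superset of
#' trials.
#'
#' @param s A `binned_session`.
#' @param drop_thresh Packet-drop fraction above which a trial is an
#'   outlier (default 0.05).
#' @param amp_sd Amplitude threshold in channel SD units (default 8).
#' @return `s` with `trials$outlier` updated; the number of flagged
#'   trials is attached as attribute `"n_flagged"`.
#' @export
flag_outlier_trials <- function(s, drop_thresh = 0.05, amp_sd = 8) {
  tr <- s$trials
  if (!nrow(tr)) {
    attr(s, "n_flagged") <- 0L
    return(s)
  }
  drop_flag <- tr$packet_drop_frac > drop_thresh

  # amplitude statistics over the session, excluding packet-drop trials
  excl <- rep(FALSE, n_bins(s))
  for (i in which(drop_flag))
    excl[tr$start_bin[i]:(tr$end_bin[i] - 1L)] <- TRUE
  ref <- s$features[!excl, , drop = FALSE]
  mu <- colMeans(ref)
  sd_ <- apply(ref, 2, stats::sd)
  usable <- is.finite(sd_) & sd_ > 0
  if (!all(usable))
    message(sum(!usable), " zero-variance channel(s) skipped in amplitude test")
  thresh <- mu + amp_sd * sd_

  amp_flag <- vapply(seq_len(nrow(tr)), function(i) {
    rows <- tr$start_bin[i]:(tr$end_bin[i] - 1L)
    any(sweep(s$features[rows, usable, drop = FALSE], 2,
              thresh[usable], ">"))
  }, logical(1))

  s$trials$outlier <- drop_flag | amp_flag
  attr(s, "n_flagged") <- sum(s$trials$outlier)
  s
}
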