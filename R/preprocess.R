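#' Windowed view of a recording
#'
#' A `window_set` holds fixed-length labelled segments cut from one record by
#' a sliding window: a channels x samples x windows array, one binary label
#' and start time per window, and optionally the per-channel normalization
#' statistics that were applied.
#'
#' @param data numeric array, channels x samples-per-window x windows.
#' @param labels integer vector (0 = non-seizure, 1 = seizure), one per window.
#' @param starts numeric vector of window start times (seconds).
#' @param fs sampling rate in Hz.
#' @param channel_labels channel label vector.
#' @param subject_id identifier string.
#' @param norm_stats optional list as returned by [zscore_fit()].
#' @return an object of class `window_set`.
#' @export
window_set <- function(data, labels, starts, fs, channel_labels,
                       subject_id = "subject", norm_stats = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(labels),
            length(starts) == length(labels),
            dim(data)[1] == length(channel_labels))
  if (!all(labels %in% c(0L, 1L)))
    gf_stop("gatformer_format_error", "window labels must be 0 or 1")
  structure(
    list(data = data, labels = as.integer(labels), starts = starts, fs = fs,
         channel_labels = channel_labels, subject_id = subject_id,
         norm_stats = norm_stats),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<window_set> %d windows of %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], x$fs))
  cat(sprintf("  labels: %d seizure / %d non-seizure%s\n",
              sum(x$labels == 1L), sum(x$labels == 0L),
              if (is.null(x$norm_stats)) "" else "; z-scored"))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [window_set].
#' @return integer count.
#' @export
n_windows <- function(ws) dim(ws$data)[3]

#' Extract one window
#' @param ws a [window_set].
#' @param i window index.
#' @return list with elements `data` (channels x samples), `label`, `start_s`.
#' @export
get_window <- function(ws, i) {
  list(data = ws$data[, , i, drop = TRUE], label = ws$labels[i],
       start_s = ws$starts[i])
}

canonical_label <- function(x) toupper(gsub("[[:space:]]+", "", x))

#' Built-in montage presets
#'
#' `"chbmit16"` is the 16-channel common bipolar set used for CHB-MIT style
#' recordings; `"tuh20"` is the 20-channel set used for TUH style recordings.
#'
#' @param name preset name.
#' @return character vector of channel labels.
#' @export
montage_preset <- function(name = c("chbmit16", "tuh20")) {
  name <- match.arg(name)
  switch(name,
    chbmit16 = c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
                 "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
                 "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
                 "F8-T8", "FZ-CZ", "CZ-PZ", "FP2-F8"),
    tuh20 = c("FP1-F7", "F7-T3", "T3-T5", "T5-O1",
              "FP2-F8", "F8-T4", "T4-T6", "T6-O2",
              "T3-C3", "C3-CZ", "CZ-C4", "C4-T4",
              "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
              "FP2-F4", "F4-C4", "C4-P4", "P4-O2"))
}

#' Select and reorder channels of a record
#'
#' Channel labels are canonicalized (whitespace removed, upper-cased) before
#' matching, so `"FP 1- F 7"` matches `"FP1-F7"`. `wanted` may also be a
#' preset name accepted by [montage_preset()].
#'
#' @param rec an [eeg_record].
#' @param wanted character vector of labels, or a preset name.
#' @return an [eeg_record] with channels reordered to match `wanted` exactly.
#' @export
select_montage <- function(rec, wanted) {
  if (length(wanted) == 1 && wanted %in% c("chbmit16", "tuh20"))
    wanted <- montage_preset(wanted)
  have <- canonical_label(rec$channel_labels)
  want <- canonical_label(wanted)
  idx <- match(want, have)
  if (anyNA(idx))
    gf_stop("gatformer_montage_error", "channel(s) not in record: %s",
            paste(wanted[is.na(idx)], collapse = ", "))
  eeg_record(rec$data[idx, , drop = FALSE], rec$fs, wanted,
             rec$seizure_intervals, rec$subject_id)
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass of the given order applied forward and backward
#' (`signal::filtfilt`) per channel, so the filter is zero-phase.
#'
#' @param rec an [eeg_record].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth design order (default 6; the resulting bandpass
#'   has twice this many poles). Orders much beyond 6 are numerically
#'   unstable in transfer-function form at EEG sampling rates.
#' @return the filtered [eeg_record]; shape and annotations preserved.
#' @export
bandpass <- function(rec, lo = 0.5, hi = 48, order = 6) {
  if (!is_scalar(lo) || !is_scalar(hi) || lo <= 0 || hi <= lo ||
      hi >= rec$fs / 2)
    gf_stop("gatformer_parameter_error",
            "need 0 < lo < hi < fs/2 (fs = %g)", rec$fs)
  if (!is_count(order))
    gf_stop("gatformer_parameter_error", "filter order must be a positive integer")
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec$data
  for (i in seq_len(nrow(out)))
    out[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  eeg_record(out, rec$fs, rec$channel_labels, rec$seizure_intervals,
             rec$subject_id)
}

#' Cut a record into overlapping fixed-length windows
#'
#' Window k starts at `k * window_s * (1 - overlap)` seconds for
#' `k = 0, ..., K - 1` with
#' `K = floor((T - window_s) / (window_s * (1 - overlap))) + 1`;
#' the trailing remainder is dropped. Starts are computed in seconds and
#' rounded to the nearest sample. Windows are labelled from the record's
#' seizure annotations by the majority-overlap rule (see [label_windows()]).
#'
#' @param rec an [eeg_record].
#' @param window_s window length in seconds (default 1).
#' @param overlap fraction of a window shared with its successor, in `[0, 1)`
#'   (default 0.5).
#' @return a [window_set].
#' @export
#' @examples
#' rec <- gen_background(sim_config(n_channels = 4, duration_s = 60, seed = 1))
#' n_windows(segment_windows(rec)) # 119 windows from 60 s
segment_windows <- function(rec, window_s = 1.0, overlap = 0.5) {
  T_s <- record_duration(rec)
  if (T_s < window_s)
    gf_stop("gatformer_segmentation_error",
            "record (%.3f s) shorter than the window (%.3f s)", T_s, window_s)
  if (overlap < 0 || overlap >= 1)
    gf_stop("gatformer_parameter_error", "overlap must be in [0, 1)")
  step <- window_s * (1 - overlap)
  K <- floor((T_s - window_s) / step + 1e-9) + 1
  Tn <- round(window_s * rec$fs)
  starts <- (seq_len(K) - 1) * step
  i0 <- round(starts * rec$fs)
  i0 <- pmin(i0, ncol(rec$data) - Tn) # guard against rounding past the end
  data <- array(0, c(nrow(rec$data), Tn, K))
  for (k in seq_len(K))
    data[, , k] <- rec$data[, (i0[k] + 1):(i0[k] + Tn), drop = FALSE]
  ws <- window_set(data, integer(K), starts, rec$fs, rec$channel_labels,
                   rec$subject_id)
  label_windows(ws, rec$seizure_intervals, window_s = window_s)
}

#' Label windows from seizure intervals
#'
#' A window is labelled seizure (1) when at least `threshold` (default 50%)
#' of its time span lies inside any seizure interval; exact ties count as
#' seizure, favouring sensitivity.
#'
#' @param ws a [window_set].
#' @param intervals two-column matrix of `[start_s, end_s)` intervals.
#' @param threshold minimum overlap fraction for a seizure label.
#' @param window_s window length in seconds; inferred from the data by
#'   default.
#' @return `ws` with recomputed labels.
#' @export
label_windows <- function(ws, intervals, threshold = 0.5, window_s = NULL) {
  intervals <- as_intervals(intervals)
  w <- window_s %||% (dim(ws$data)[2] / ws$fs)
  ovl <- numeric(length(ws$starts))
  for (k in seq_len(nrow(intervals))) {
    lo <- pmax(ws$starts, intervals[k, 1])
    hi <- pmin(ws$starts + w, intervals[k, 2])
    ovl <- ovl + pmax(hi - lo, 0) # intervals are disjoint, so sums are exact
  }
  ws$labels <- as.integer(ovl >= threshold * w - 1e-12)
  ws
}

# Oversample the minority class (with replacement) until both classes have
# equal counts; returns the expanded index vector, majority class untouched.
balance_indices <- function(labels, seed) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0 || length(neg) == 0)
    gf_stop("gatformer_balance_error",
            "both classes must be present to balance (got %d pos, %d neg)",
            length(pos), length(neg))
  if (length(pos) == length(neg)) return(seq_along(labels))
  minority <- if (length(pos) < length(neg)) pos else neg
  deficit <- abs(length(pos) - length(neg))
  extra <- local_seed(seed, sample(minority, deficit, replace = TRUE))
  c(seq_along(labels), extra)
}

#' Balance classes 1:1 by oversampling
#'
#' Minority-class windows are resampled with replacement (whole-window
#' duplicates, no augmentation) until class counts are equal; the majority
#' class is untouched. Deterministic given `seed`.
#'
#' @param ws a [window_set] containing both classes.
#' @param seed integer seed.
#' @return a balanced [window_set].
#' @export
balance_1to1 <- function(ws, seed = 1L) {
  idx <- balance_indices(ws$labels, seed)
  window_set(ws$data[, , idx, drop = FALSE], ws$labels[idx], ws$starts[idx],
             ws$fs, ws$channel_labels, ws$subject_id, ws$norm_stats)
}

#' Fit per-channel normalization statistics
#'
#' Mean and standard deviation per channel, pooled over all windows and
#' samples of `ws` (which should be the training portion only). Standard
#' deviations are floored at `1e-8` so constant channels map to zeros.
#'
#' @param ws a [window_set] of training windows.
#' @return list with numeric vectors `mean` and `sd` (one entry per channel).
#' @export
zscore_fit <- function(ws) {
  d <- dim(ws$data)
  flat <- ws$data
  dim(flat) <- c(d[1], d[2] * d[3])
  m <- rowMeans(flat)
  s <- sqrt(pmax(rowMeans(flat^2) - m^2, 0))
  list(mean = m, sd = pmax(s, 1e-8))
}

#' Apply normalization statistics
#'
#' Transforms each channel to `(x - mean) / sd` using statistics fitted with
#' [zscore_fit()] (typically on the training folds only).
#'
#' @param ws a [window_set].
#' @param stats list from [zscore_fit()].
#' @return the normalized [window_set], with `norm_stats` recorded.
#' @export
zscore_apply <- function(ws, stats) {
  ws$data <- (ws$data - stats$mean) / stats$sd # recycles down dim 1
  ws$norm_stats <- stats
  ws
}
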