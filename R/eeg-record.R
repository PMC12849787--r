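#' Construct a continuous multi-channel EEG record
#'
#' The basic container for a recording: a channels-by-samples matrix in
#' microvolts, a sampling rate, bipolar-montage channel labels (e.g.
#' `"FP1-F7"`) and half-open seizure annotation intervals in seconds.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel labels, one per
#'   row of `data`.
#' @param seizure_intervals two-column numeric matrix (or empty) of
#'   `[start_s, end_s)` seizure intervals, seconds from record start. Must be
#'   sorted, pairwise disjoint and inside the record.
#' @param subject_id identifier string.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_labels,
                       seizure_intervals = empty_intervals(),
                       subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data))
    gf_stop("gatformer_format_error", "`data` must be a numeric matrix (channels x samples)")
  if (!is_scalar(fs) || fs <= 0)
    gf_stop("gatformer_format_error", "`fs` must be a positive scalar (Hz)")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    gf_stop("gatformer_format_error",
            "%d channel labels for %d data rows", length(channel_labels), nrow(data))
  if (anyDuplicated(channel_labels))
    gf_stop("gatformer_format_error", "channel labels must be unique")
  seizure_intervals <- as_intervals(seizure_intervals)
  dur <- ncol(data) / fs
  if (nrow(seizure_intervals)) {
    if (any(seizure_intervals[, 1] < 0) || any(seizure_intervals[, 2] > dur + 1e-9))
      gf_stop("gatformer_format_error", "seizure intervals must lie within [0, duration)")
    if (any(seizure_intervals[, 2] <= seizure_intervals[, 1]))
      gf_stop("gatformer_format_error", "seizure intervals must have end > start")
    if (is.unsorted(seizure_intervals[, 1]))
      gf_stop("gatformer_format_error", "seizure intervals must be sorted by start")
    if (nrow(seizure_intervals) > 1 &&
        any(seizure_intervals[-1, 1] < seizure_intervals[-nrow(seizure_intervals), 2]))
      gf_stop("gatformer_format_error", "seizure intervals must be disjoint")
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         seizure_intervals = seizure_intervals, subject_id = subject_id),
    class = "eeg_record"
  )
}

empty_intervals <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_s", "end_s")))
}

as_intervals <- function(x) {
  if (is.null(x) || length(x) == 0) return(empty_intervals())
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  x <- matrix(as.numeric(x), ncol = 2)
  colnames(x) <- c("start_s", "end_s")
  x
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> subject '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, record_duration(x)))
  n <- nrow(x$seizure_intervals)
  if (n == 0) {
    cat("  no seizure annotations\n")
  } else {
    cat(sprintf("  %d seizure interval(s), %.1f s total\n",
                n, sum(x$seizure_intervals[, 2] - x$seizure_intervals[, 1])))
  }
  invisible(x)
}

#' Record duration in seconds
#' @param rec an [eeg_record].
#' @return duration in seconds.
#' @export
record_duration <- function(rec) ncol(rec$data) / rec$fs
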