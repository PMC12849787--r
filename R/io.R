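#' Read an EEG recording from disk
#'
#' Supports two formats: `"edf"` (European Data Format, 16-bit; seizure
#' annotations are read from a CSV sidecar with columns
#' `start_s,end_s,label`) and `"rds"`, the R-native serialized bundle written
#' by [write_record()] (round-trips the record exactly).
#'
#' @param path file path.
#' @param format `"edf"` or `"rds"`; guessed from the extension by default.
#' @param annotations optional path to the annotation CSV sidecar (EDF only).
#'   Defaults to `<stem>_annotations.csv` next to the EDF file if present.
#' @return an [eeg_record].
#' @export
read_record <- function(path, format = c("auto", "edf", "rds"),
                        annotations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path) || dir.exists(path))
    gf_stop("gatformer_io_error", "cannot read '%s': no such file", path)
  if (file.size(path) == 0)
    gf_stop("gatformer_io_error", "cannot read '%s': file is empty", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds"
  if (format == "rds") {
    rec <- readRDS(path)
    if (!inherits(rec, "eeg_record"))
      gf_stop("gatformer_io_error", "'%s' does not contain an eeg_record", path)
    return(rec)
  }
  read_edf(path, annotations)
}

#' Write an EEG recording to disk
#'
#' For `"edf"`, data are quantized to 16 bits with per-channel symmetric
#' physical ranges and one data record per second (a trailing partial second
#' is dropped); annotations go to a `<stem>_annotations.csv` sidecar. For
#' `"rds"` the record is serialized losslessly.
#'
#' @param rec an [eeg_record].
#' @param path output path.
#' @param format `"edf"` or `"rds"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, format = c("auto", "edf", "rds")) {
  format <- match.arg(format)
  if (!inherits(rec, "eeg_record"))
    gf_stop("gatformer_io_error", "`rec` must be an eeg_record")
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds"
  if (format == "rds") {
    saveRDS(rec, path)
  } else {
    write_edf(rec, path)
    write_annotation_csv(rec$seizure_intervals, annotation_sidecar(path))
  }
  invisible(path)
}

annotation_sidecar <- function(edf_path) {
  sub("\\.edf$", "_annotations.csv", edf_path, ignore.case = TRUE)
}

write_annotation_csv <- function(intervals, path) {
  df <- data.frame(start_s = intervals[, 1], end_s = intervals[, 2],
                   label = rep("seizure", nrow(intervals)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_annotation_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df)))
    gf_stop("gatformer_format_error",
            "annotation sidecar '%s' lacks start_s/end_s columns", path)
  if ("label" %in% names(df)) df <- df[df$label == "seizure", , drop = FALSE]
  as_intervals(df[, c("start_s", "end_s")])
}

# ---- minimal EDF (16-bit) writer/reader ------------------------------------
# Fixed-layout ASCII header (256 bytes + 256 per signal), int16 little-endian
# samples interleaved per one-second data record.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path) {
  fs <- round(rec$fs)
  if (abs(fs - rec$fs) > 1e-9)
    gf_stop("gatformer_io_error", "EDF writer requires an integer sampling rate")
  M <- nrow(rec$data)
  nrec <- floor(ncol(rec$data) / fs)
  if (nrec < 1)
    gf_stop("gatformer_io_error", "record shorter than one EDF data record (1 s)")
  pm <- pmax(ceiling(apply(abs(rec$data), 1, max)), 1) # symmetric integer range
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad("gatformer synthetic EEG", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(256 * (M + 1), 8), pad("", 44),
    pad(nrec, 8), pad("1", 8), pad(M, 4),
    paste(vapply(rec$channel_labels, pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), M), collapse = ""),
    paste(rep(pad("uV", 8), M), collapse = ""),
    paste(vapply(-pm, pad, "", width = 8), collapse = ""),
    paste(vapply(pm, pad, "", width = 8), collapse = ""),
    paste(rep(pad("-32768", 8), M), collapse = ""),
    paste(rep(pad("32767", 8), M), collapse = ""),
    paste(rep(pad("", 80), M), collapse = ""),
    paste(rep(pad(fs, 8), M), collapse = ""),
    paste(rep(pad("", 32), M), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  gain <- 2 * pm / 65535 # physical units per digital unit
  dig <- round(sweep(rec$data[, seq_len(nrec * fs), drop = FALSE], 1, gain, "/"))
  dig <- pmin(pmax(dig, -32768), 32767)
  # record-major, signal blocks inside each record
  out <- integer(nrec * fs * M)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- t(dig[, cols, drop = FALSE]) # fs x M, columns are signals
    out[((r - 1) * fs * M + 1):(r * fs * M)] <- as.integer(block)
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

read_edf <- function(path, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (length(x) == 0 || nchar(x, type = "bytes") < n)
      gf_stop("gatformer_io_error", "truncated EDF header in '%s'", path)
    trimws(x)
  }
  invisible(rd(8)) # version
  subject_id <- rd(80)
  invisible(rd(80)); invisible(rd(8)); invisible(rd(8)); invisible(rd(8))
  invisible(rd(44))
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  M <- as.integer(rd(4))
  if (is.na(M) || M < 1 || is.na(nrec) || nrec < 1)
    gf_stop("gatformer_io_error", "malformed EDF header in '%s'", path)
  labels <- vapply(seq_len(M), function(i) rd(16), "")
  invisible(vapply(seq_len(M), function(i) rd(80), "")) # transducer
  invisible(vapply(seq_len(M), function(i) rd(8), ""))  # physical dimension
  phys_min <- as.numeric(vapply(seq_len(M), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(M), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(M), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(M), function(i) rd(8), ""))
  invisible(vapply(seq_len(M), function(i) rd(80), "")) # prefiltering
  spr <- as.integer(vapply(seq_len(M), function(i) rd(8), ""))
  invisible(vapply(seq_len(M), function(i) rd(32), ""))
  if (length(unique(spr)) != 1)
    gf_stop("gatformer_format_error",
            "EDF signals with differing sampling rates are not supported")
  fs <- spr[1] / dur
  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2,
                 endian = "little")
  if (length(raw) < nrec * sum(spr))
    gf_stop("gatformer_io_error", "truncated EDF data in '%s'", path)
  data <- matrix(0, M, nrec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(nrec)) {
    base <- (r - 1) * sum(spr)
    for (i in seq_len(M)) {
      seg <- raw[(base + (i - 1) * spr[i] + 1):(base + i * spr[i])]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        phys_min[i] + (seg - dig_min[i]) * gain[i]
    }
  }
  iv <- empty_intervals()
  sidecar <- annotations %||% annotation_sidecar(path)
  if (file.exists(sidecar)) iv <- read_annotation_csv(sidecar)
  eeg_record(data, fs, labels, iv, subject_id)
}
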