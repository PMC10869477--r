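# EDF (European Data Format) 16-bit read/write in base R.
#
# Only the continuous-recording EDF core is supported: one sampling rate per
# selected channel, int16 samples, record-major layout. EDF+ annotation
# channels are not parsed; seizure annotations travel in the CSV sidecar
# format (see read_annotations). Signals are taken as microvolts as declared
# by the header; no re-scaling beyond the EDF gain/offset is applied.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

# EDF numeric header fields are 8 ASCII chars; emit the longest plain decimal
# representation that fits (integers exactly, otherwise trimmed decimals).
fmt_num8 <- function(x) {
  if (x == round(x) && nchar(sprintf("%.0f", x)) <= 8L) {
    return(pad_ascii(sprintf("%.0f", x), 8L))
  }
  for (digits in 6:0) {
    s <- formatC(x, digits = digits, format = "f")
    if (nchar(s) <= 8L) return(pad_ascii(s, 8L))
  }
  rlang::abort(sprintf("value %g does not fit an 8-char EDF header field", x),
               class = "seizadapt_error")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range covering
#' the data, so a write/read round trip is exact up to that quantization. The
#' recording is truncated to a whole number of 1-second data records.
#'
#' @param recording A [new_recording()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  assert_that(inherits(recording, "seiz_recording"),
              "`recording` must be a seiz_recording")
  x <- recording$data
  fs <- recording$fs
  assert_that(fs == as.integer(fs), "EDF writer requires an integer Hz rate")
  n_ch <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  assert_that(n_rec >= 1, "recording shorter than one 1-second data record")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]

  phys_max <- max(1e-6, max(abs(x)))
  phys_max <- ceiling(phys_max)
  dig_max <- 32767L
  scale <- dig_max / phys_max
  xd <- matrix(as.integer(round(x * scale)), n_ch)
  xd[xd > dig_max] <- dig_max
  xd[xd < -dig_max] <- -dig_max

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(recording$subject_id, 80),
    pad_ascii(recording$record_id, 80),
    "01.01.00", "00.00.00",
    pad_ascii(256L * (n_ch + 1L), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8),
    pad_ascii(1, 8),
    pad_ascii(n_ch, 4)
  )
  sig <- paste0(
    paste(pad_ascii(recording$channel_names, 16), collapse = ""),
    paste(rep(pad_ascii("", 80), n_ch), collapse = ""),
    paste(rep(pad_ascii("uV", 8), n_ch), collapse = ""),
    paste(rep(fmt_num8(-phys_max), n_ch), collapse = ""),
    paste(rep(fmt_num8(phys_max), n_ch), collapse = ""),
    paste(rep(fmt_num8(-dig_max), n_ch), collapse = ""),
    paste(rep(fmt_num8(dig_max), n_ch), collapse = ""),
    paste(rep(pad_ascii("", 80), n_ch), collapse = ""),
    paste(rep(fmt_num8(fs), n_ch), collapse = ""),
    paste(rep(pad_ascii("", 32), n_ch), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  # record-major: for each 1 s record, all channels' samples in sequence
  dim(xd) <- c(n_ch, fs, n_rec)
  for (r in seq_len(n_rec)) {
    writeBin(as.integer(t(xd[, , r])), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  trimws(readChar(con, n, useBytes = TRUE))
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param montage Optional character vector of channel labels to retain, in
#'   the desired order. Channels not in the montage are dropped; the reader
#'   never silently reorders beyond following the montage list. `NULL` keeps
#'   all channels in file order.
#' @param min_channels Recordings with fewer retained channels than this are
#'   rejected (the usual scalp-EEG screening keeps only >= 23-electrode
#'   recordings).
#' @param subject_id Optional subject id; defaults to the EDF patient field
#'   (or the file name if blank).
#' @param annotations Optional annotation table for this record (columns
#'   `onset_s`, `offset_s`).
#' @return A [new_recording()] object.
#' @export
read_edf <- function(path, montage = NULL, min_channels = 0L,
                     subject_id = NULL, annotations = NULL) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  version <- read_ascii(con, 8)
  assert_that(version == "0",
              sprintf("unreadable EDF header in %s (bad version field)", path))
  patient <- read_ascii(con, 80)
  record_field <- read_ascii(con, 80)
  invisible(readChar(con, 16, useBytes = TRUE))  # date + time
  header_bytes <- as.integer(read_ascii(con, 8))
  invisible(readChar(con, 44, useBytes = TRUE))
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  assert_that(!is.na(ns) && ns >= 1 && !is.na(n_rec) && n_rec >= 1 &&
                !is.na(rec_dur) && rec_dur > 0,
              sprintf("unreadable EDF header in %s", path))
  assert_that(header_bytes == 256L * (ns + 1L),
              sprintf("unreadable EDF header in %s (byte count mismatch)", path))

  rd_field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- rd_field(16)
  invisible(rd_field(80))                       # transducer
  invisible(rd_field(8))                        # physical dimension
  phys_min <- as.numeric(rd_field(8))
  phys_max <- as.numeric(rd_field(8))
  dig_min <- as.numeric(rd_field(8))
  dig_max <- as.numeric(rd_field(8))
  invisible(rd_field(80))                       # prefiltering
  ns_per_rec <- as.integer(rd_field(8))
  invisible(rd_field(32))                       # reserved

  if (is.null(montage)) {
    keep <- seq_len(ns)
  } else {
    keep <- match(montage, labels)
    missing <- montage[is.na(keep)]
    if (length(missing) == length(montage)) {
      rlang::abort(sprintf("no montage channel found in %s", path),
                   class = "seizadapt_error")
    }
    keep <- keep[!is.na(keep)]
  }
  rates <- ns_per_rec[keep] / rec_dur
  if (length(unique(rates)) > 1L) {
    rlang::abort(sprintf(
      "mixed sampling rates across selected channels in %s: %s", path,
      paste(sprintf("%s=%g Hz", labels[keep], rates), collapse = ", ")),
      class = "seizadapt_error")
  }
  if (length(keep) < min_channels) {
    rlang::abort(sprintf(
      "recording %s rejected: %d channel(s) retained, minimum is %d",
      path, length(keep), min_channels), class = "seizadapt_error")
  }

  samples_per_rec <- sum(ns_per_rec)
  raw <- readBin(con, "integer", n = samples_per_rec * n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  assert_that(length(raw) == samples_per_rec * n_rec,
              sprintf("truncated EDF data in %s", path))

  fs <- rates[1]
  offsets <- c(0L, cumsum(ns_per_rec))
  out <- matrix(0, length(keep), ns_per_rec[keep[1]] * n_rec)
  for (ci in seq_along(keep)) {
    s <- keep[ci]
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    idx <- as.vector(outer(seq_len(ns_per_rec[s]) + offsets[s],
                           (seq_len(n_rec) - 1L) * samples_per_rec, "+"))
    out[ci, ] <- (raw[idx] - dig_min[s]) * gain + phys_min[s]
  }

  sid <- subject_id %||% (if (nzchar(patient)) patient else basename(path))
  rid <- if (nzchar(record_field)) record_field else basename(path)
  new_recording(subject_id = sid, data = out, fs = fs,
                channel_names = labels[keep],
                annotations = annotations %||% empty_annotations(),
                record_id = rid)
}
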