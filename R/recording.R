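#' Construct a multichannel EEG recording object
#'
#' A recording bundles a channels-by-samples signal matrix (microvolts), its
#' sampling rate, channel names, and the seizure annotations attached to it.
#' All times are seconds from recording start; seizure intervals are half-open
#' `[onset_s, offset_s)`.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector, one name per row of `data`.
#' @param annotations Data frame with columns `onset_s`, `offset_s`; may have
#'   zero rows for seizure-free records. Must be sorted by onset and
#'   non-overlapping.
#' @param record_id Character scalar naming this record (defaults to
#'   `subject_id`).
#'
#' @return An object of class `seiz_recording`.
#' @export
new_recording <- function(subject_id, data, fs, channel_names,
                          annotations = empty_annotations(),
                          record_id = subject_id) {
  assert_that(is.character(subject_id) && length(subject_id) == 1L,
              "`subject_id` must be a single string")
  assert_that(is.matrix(data) && is.numeric(data),
              "`data` must be a numeric channels x samples matrix")
  assert_that(is_scalar_num(fs) && fs > 0, "`fs` must be a positive scalar")
  assert_that(length(channel_names) == nrow(data),
              sprintf("`data` has %d rows but %d channel names were given",
                      nrow(data), length(channel_names)))
  annotations <- validate_annotations(annotations,
                                      duration_s = ncol(data) / fs)
  structure(
    list(subject_id = subject_id, record_id = record_id, data = data,
         fs = fs, channel_names = as.character(channel_names),
         annotations = annotations),
    class = "seiz_recording"
  )
}

empty_annotations <- function() {
  tibble::tibble(onset_s = numeric(0), offset_s = numeric(0))
}

validate_annotations <- function(ann, duration_s = Inf) {
  ann <- tibble::as_tibble(ann)
  assert_that(all(c("onset_s", "offset_s") %in% names(ann)),
              "annotations need columns `onset_s` and `offset_s`")
  if (nrow(ann) == 0L) return(ann[c("onset_s", "offset_s")])
  bad <- which(ann$offset_s <= ann$onset_s)
  assert_that(length(bad) == 0L,
              sprintf("annotation row %d has offset <= onset", bad[1]))
  assert_that(all(ann$onset_s >= 0) && all(ann$offset_s <= duration_s + 1e-9),
              "annotations must lie within [0, recording duration]")
  ann <- ann[order(ann$onset_s), c("onset_s", "offset_s")]
  if (nrow(ann) > 1L) {
    overlap <- any(ann$onset_s[-1] < ann$offset_s[-nrow(ann)])
    assert_that(!overlap, "annotations must be non-overlapping")
  }
  ann
}

#' @export
print.seiz_recording <- function(x, ...) {
  cat(sprintf("<seiz_recording> subject %s, record %s\n", x$subject_id,
              x$record_id))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording A `seiz_recording`.
#' @return Numeric scalar.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}
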