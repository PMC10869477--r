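# Seizure annotation plumbing. The canonical on-disk format is a plain CSV
# with columns record_id, onset_s, offset_s (seconds from recording start,
# half-open [onset, offset)). A convenience parser for CHB-MIT
# "-summary.txt" listings normalizes them into the same shape.

#' Read a seizure annotation table
#'
#' @param path CSV file with columns `record_id`, `onset_s`, `offset_s`. An
#'   empty file (header only, or zero bytes) yields an empty table, the
#'   representation of a seizure-free record set.
#' @return A tibble sorted by `record_id` then `onset_s`, validated so that
#'   every `offset_s > onset_s`.
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  if (file.size(path) == 0L) {
    return(tibble::tibble(record_id = character(0), onset_s = numeric(0),
                          offset_s = numeric(0)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("record_id", "onset_s", "offset_s") %in% names(df)),
              "annotation file needs columns record_id, onset_s, offset_s")
  if (nrow(df) > 0) {
    bad <- which(!(df$offset_s > df$onset_s))
    if (length(bad)) {
      rlang::abort(sprintf(
        "annotation row %d (record %s): offset_s (%g) <= onset_s (%g)",
        bad[1], df$record_id[bad[1]], df$offset_s[bad[1]], df$onset_s[bad[1]]),
        class = "seizadapt_error")
    }
    assert_that(all(df$onset_s >= 0), "onset_s must be >= 0")
  }
  out <- tibble::as_tibble(df[c("record_id", "onset_s", "offset_s")])
  out[order(out$record_id, out$onset_s), ]
}

#' Write a seizure annotation table
#' @param annotations Data frame with `record_id`, `onset_s`, `offset_s`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)[c("record_id", "onset_s", "offset_s")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse a CHB-MIT style summary listing into the canonical annotation table
#'
#' Understands the `File Name:` / `Seizure Start Time:` / `Seizure End Time:`
#' blocks of the CHB-MIT `*-summary.txt` files (including the numbered
#' `Seizure 1 Start Time:` variant). The CSV format of [read_annotations()]
#' remains canonical; this is a convenience normalizer.
#'
#' @param path Path to a summary text file.
#' @return A tibble with `record_id`, `onset_s`, `offset_s`.
#' @export
parse_chb_summary <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- NA_character_
  out <- list()
  onset <- NA_real_
  for (ln in lines) {
    if (grepl("^\\s*File Name\\s*:", ln)) {
      rec <- trimws(sub("^\\s*File Name\\s*:", "", ln))
      rec <- sub("\\.edf$", "", rec)
    } else if (grepl("Seizure.*Start Time\\s*:", ln)) {
      onset <- as.numeric(gsub("[^0-9.]", "", sub(".*:", "", ln)))
    } else if (grepl("Seizure.*End Time\\s*:", ln)) {
      offset <- as.numeric(gsub("[^0-9.]", "", sub(".*:", "", ln)))
      assert_that(!is.na(rec) && !is.na(onset),
                  "malformed summary: end time before start time/file name")
      out[[length(out) + 1L]] <- tibble::tibble(
        record_id = rec, onset_s = onset, offset_s = offset)
      onset <- NA_real_
    }
  }
  if (!length(out)) {
    return(tibble::tibble(record_id = character(0), onset_s = numeric(0),
                          offset_s = numeric(0)))
  }
  res <- dplyr::bind_rows(out)
  res[order(res$record_id, res$onset_s), ]
}

#' Annotations for one record
#' @param annotations Canonical annotation table.
#' @param record_id Record to select.
#' @return Tibble with `onset_s`, `offset_s` for that record, sorted.
#' @export
annotations_for_record <- function(annotations, record_id) {
  sel <- annotations[annotations$record_id == record_id, ]
  tibble::as_tibble(sel[order(sel$onset_s), c("onset_s", "offset_s")])
}
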