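#' Construct a labeled window set
#'
#' The central training container: a channels x samples x windows array plus a
#' tibble of per-window metadata (subject, record, start time, binary label:
#' 0 = inter-ictal, 1 = pre-ictal). A preprocessing-config hash travels with
#' the set so archives produced under incompatible settings cannot be merged.
#'
#' @param x Numeric array `(C, T, n)`; `n` may be 0.
#' @param meta Tibble with columns `subject_id`, `record_id`, `start_s`, `y`
#'   and one row per window.
#' @param fs Sampling rate in Hz.
#' @param window_s Window duration in seconds (`T == window_s * fs`).
#' @param channel_names Character vector of length `C`.
#' @param config_hash Hash string of the preprocessing configuration.
#' @return A `window_set` object.
#' @export
new_window_set <- function(x, meta, fs, window_s, channel_names,
                           config_hash = "unset") {
  assert_that(is.array(x) && length(dim(x)) == 3L,
              "`x` must be a (channels, samples, windows) array")
  meta <- tibble::as_tibble(meta)
  assert_that(all(c("subject_id", "record_id", "start_s", "y") %in% names(meta)),
              "`meta` needs columns subject_id, record_id, start_s, y")
  assert_that(nrow(meta) == dim(x)[3],
              "`meta` must have one row per window")
  assert_that(all(meta$y %in% c(0, 1)), "labels must be 0 or 1")
  assert_that(dim(x)[2] == round(window_s * fs),
              "sample count must equal window_s * fs")
  assert_that(length(channel_names) == dim(x)[1],
              "one channel name per array row required")
  structure(
    list(x = x, meta = meta, fs = fs, window_s = window_s,
         channel_names = as.character(channel_names),
         config_hash = config_hash),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  n <- dim(x$x)[3]
  cat(sprintf(
    "<window_set> %d window(s) of %g s (%d ch x %d samples @ %g Hz)\n",
    n, x$window_s, dim(x$x)[1], dim(x$x)[2], x$fs))
  if (n > 0) {
    tab <- table(factor(x$meta$y, levels = c(0, 1)))
    cat(sprintf("  inter-ictal: %d, pre-ictal: %d, subjects: %d\n",
                tab[["0"]], tab[["1"]],
                length(unique(x$meta$subject_id))))
  }
  invisible(x)
}

#' Number of windows in a set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$x)[3]

#' Subset a window set by window index
#' @param ws A `window_set`.
#' @param idx Integer indices of windows to keep.
#' @return A `window_set` with the selected windows, in `idx` order.
#' @export
subset_windows <- function(ws, idx) {
  idx <- as.integer(idx)
  assert_that(all(idx >= 1 & idx <= n_windows(ws)), "window index out of range")
  new_window_set(ws$x[, , idx, drop = FALSE], ws$meta[idx, ], ws$fs,
                 ws$window_s, ws$channel_names, ws$config_hash)
}

#' Concatenate window sets
#'
#' Sets must share window geometry and preprocessing config hash; merging
#' archives produced under different preprocessing is refused.
#'
#' @param ... `window_set` objects.
#' @return A single merged `window_set`.
#' @export
merge_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  assert_that(length(sets) >= 1L, "nothing to merge")
  ref <- sets[[1]]
  for (s in sets[-1]) {
    assert_that(inherits(s, "window_set"), "all inputs must be window_sets")
    assert_that(dim(s$x)[1] == dim(ref$x)[1] && dim(s$x)[2] == dim(ref$x)[2] &&
                  s$fs == ref$fs && s$window_s == ref$window_s,
                "cannot merge window sets with different window geometry")
    assert_that(identical(s$config_hash, ref$config_hash),
                sprintf(
                  "preprocessing config hash mismatch (%s vs %s): refusing to merge incompatible archives",
                  ref$config_hash, s$config_hash))
  }
  xs <- lapply(sets, function(s) s$x)
  n <- sum(vapply(xs, function(a) dim(a)[3], 0L))
  x <- array(0, c(dim(ref$x)[1], dim(ref$x)[2], n))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[3]
    if (k > 0) x[, , at + seq_len(k)] <- a
    at <- at + k
  }
  meta <- dplyr::bind_rows(lapply(sets, function(s) s$meta))
  new_window_set(x, meta, ref$fs, ref$window_s, ref$channel_names,
                 ref$config_hash)
}

#' Save a window set archive
#'
#' Lossless round trip of window tensors, labels, subject ids, and provenance
#' times, together with the preprocessing config hash.
#'
#' @param ws A `window_set`.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_windows <- function(ws, path) {
  assert_that(inherits(ws, "window_set"), "`ws` must be a window_set")
  saveRDS(ws, path)
  invisible(path)
}

#' Load a window set archive
#' @param path Path written by [save_windows()].
#' @return A `window_set`.
#' @export
load_windows <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  ws <- readRDS(path)
  assert_that(inherits(ws, "window_set"),
              sprintf("%s is not a window archive", path))
  ws
}
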