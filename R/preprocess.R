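#' Preprocessing configuration
#'
#' Defaults follow the standard scalp-EEG seizure-prediction recipe: 50 Hz
#' notch, 0.5-70 Hz band-pass, a 1-hour pre-ictal horizon before each seizure
#' onset, exclusion of the ictal interval plus a post-ictal guard (default
#' 1 hour, configurable — conventions in the literature are hour-scale), and
#' non-overlapping 10-second windows normalized per channel.
#'
#' @param notch_hz Mains notch frequency (Hz).
#' @param band_hz Length-2 numeric band-pass edges (Hz).
#' @param preictal_horizon_s Pre-ictal horizon before each onset (seconds).
#' @param postictal_exclusion_s Post-ictal guard after each offset (seconds).
#' @param window_s Window duration (seconds).
#' @param min_channels Minimum retained channel count for a recording.
#' @param balance_seed Seed for majority-class under-sampling.
#' @param notch_q Quality factor of the notch biquad.
#' @param balance_before_split If `TRUE`, under-sample before splitting
#'   (strict-reproduction mode); the default balances the training set only,
#'   after splitting, to keep test distributions honest.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(notch_hz = 50,
                              band_hz = c(0.5, 70),
                              preictal_horizon_s = 3600,
                              postictal_exclusion_s = 3600,
                              window_s = 10,
                              min_channels = 23,
                              balance_seed = 1L,
                              notch_q = 30,
                              balance_before_split = FALSE) {
  assert_that(length(band_hz) == 2L && band_hz[1] < band_hz[2],
              "`band_hz` must be (low, high) with low < high")
  assert_that(preictal_horizon_s > window_s,
              "`preictal_horizon_s` must exceed `window_s`")
  structure(
    list(notch_hz = notch_hz, band_hz = as.numeric(band_hz),
         preictal_horizon_s = preictal_horizon_s,
         postictal_exclusion_s = postictal_exclusion_s,
         window_s = window_s, min_channels = as.integer(min_channels),
         balance_seed = as.integer(balance_seed), notch_q = notch_q,
         balance_before_split = balance_before_split),
    class = "preprocess_config"
  )
}

preprocess_hash <- function(config) {
  config_hash(config[c("notch_hz", "band_hz", "preictal_horizon_s",
                       "postictal_exclusion_s", "window_s", "min_channels")])
}

# RBJ notch biquad coefficients at f0 Hz with quality factor q.
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch and band-pass filter a recording (zero phase)
#'
#' Applies a second-order IIR notch (quality factor `notch_q`) at `notch_hz`
#' and a 4th-order Butterworth band-pass over `band_hz`, each forward-backward
#' (`signal::filtfilt`) so features are not shifted in time. Requires
#' `fs > 2 * band_hz[2]`.
#'
#' @param recording A [new_recording()] object.
#' @param config A [preprocess_config()].
#' @return The filtered recording (same shape).
#' @export
apply_filters <- function(recording, config = preprocess_config()) {
  assert_that(inherits(recording, "seiz_recording"),
              "`recording` must be a seiz_recording")
  fs <- recording$fs
  hi <- config$band_hz[2]
  assert_that(fs > 2 * hi,
              sprintf("sampling rate %g Hz cannot represent the %g Hz band edge (need fs > %g Hz)",
                      fs, hi, 2 * hi))
  bp <- signal::butter(2, config$band_hz / (fs / 2), type = "pass")
  nt <- notch_biquad(config$notch_hz, fs, config$notch_q)
  x <- recording$data
  for (c in seq_len(nrow(x))) {
    v <- signal::filtfilt(signal::Arma(b = nt$b, a = nt$a), x[c, ])
    v <- signal::filtfilt(bp, v)
    x[c, ] <- v
  }
  recording$data <- x
  recording
}

#' Label a recording's timeline into pre-ictal / inter-ictal / excluded
#'
#' For each seizure onset `t`, `[t - horizon, t)` is pre-ictal (clipped at the
#' record start and at earlier exclusion zones); `[onset, offset)` (ictal) and
#' `[offset, offset + postictal_exclusion_s)` are excluded; all remaining time
#' is inter-ictal. Exclusion zones take priority over pre-ictal horizons, so
#' overlapping structures resolve to: excluded > pre-ictal > inter-ictal.
#'
#' @param recording A [new_recording()] with validated annotations.
#' @param config A [preprocess_config()].
#' @return A tibble of disjoint intervals with columns `record_id`, `start_s`,
#'   `end_s`, `label` (one of `"interictal"`, `"preictal"`, `"excluded"`),
#'   sorted by `start_s` and covering `[0, duration)`.
#' @export
label_intervals <- function(recording, config = preprocess_config()) {
  dur <- recording_duration(recording)
  ann <- recording$annotations
  if (nrow(ann) == 0L) {
    return(tibble::tibble(record_id = recording$record_id, start_s = 0,
                          end_s = dur, label = "interictal"))
  }
  excl <- cbind(ann$onset_s, pmin(dur, ann$offset_s + config$postictal_exclusion_s))
  pre <- cbind(pmax(0, ann$onset_s - config$preictal_horizon_s), ann$onset_s)

  # Sweep over breakpoints; labels by priority excluded > preictal.
  pts <- sort(unique(pmin(pmax(c(0, dur, excl, pre), 0), dur)))
  pts <- pts[pts <= dur]
  starts <- pts[-length(pts)]
  ends <- pts[-1]
  mid <- (starts + ends) / 2
  in_any <- function(t, iv) {
    if (nrow(iv) == 0) return(rep(FALSE, length(t)))
    vapply(t, function(ti) any(ti >= iv[, 1] & ti < iv[, 2]), TRUE)
  }
  label <- ifelse(in_any(mid, excl), "excluded",
                  ifelse(in_any(mid, pre), "preictal", "interictal"))
  out <- tibble::tibble(record_id = recording$record_id, start_s = starts,
                        end_s = ends, label = label)
  # merge adjacent intervals with equal labels
  out$grp <- cumsum(c(TRUE, label[-1] != label[-length(label)]))
  out <- out %>%
    dplyr::group_by(.data$record_id, .data$grp) %>%
    dplyr::summarise(start_s = min(.data$start_s), end_s = max(.data$end_s),
                     label = .data$label[1], .groups = "drop") %>%
    dplyr::select("record_id", "start_s", "end_s", "label") %>%
    dplyr::arrange(.data$start_s)
  out[out$end_s > out$start_s, ]
}

#' Cut labeled intervals into non-overlapping windows
#'
#' Windows tile each pre-ictal / inter-ictal interval left-to-right with
#' stride equal to the window length; a partial trailing segment is discarded;
#' excluded intervals produce nothing.
#'
#' @param recording A (filtered) [new_recording()].
#' @param intervals Output of [label_intervals()].
#' @param config A [preprocess_config()].
#' @return A [new_window_set()]; windows are not yet normalized.
#' @export
extract_windows <- function(recording, intervals,
                            config = preprocess_config()) {
  fs <- recording$fs
  wlen <- as.integer(round(config$window_s * fs))
  starts <- numeric(0)
  labels <- numeric(0)
  use <- intervals[intervals$label %in% c("interictal", "preictal"), ]
  for (i in seq_len(nrow(use))) {
    k <- floor((use$end_s[i] - use$start_s[i]) / config$window_s)
    if (k >= 1) {
      st <- use$start_s[i] + (seq_len(k) - 1) * config$window_s
      starts <- c(starts, st)
      labels <- c(labels, rep(ifelse(use$label[i] == "preictal", 1, 0), k))
    }
  }
  n <- length(starts)
  x <- array(0, c(nrow(recording$data), wlen, n))
  for (j in seq_len(n)) {
    i0 <- as.integer(round(starts[j] * fs))
    x[, , j] <- recording$data[, i0 + seq_len(wlen), drop = FALSE]
  }
  meta <- tibble::tibble(subject_id = rep(recording$subject_id, n),
                         record_id = rep(recording$record_id, n),
                         start_s = starts, y = labels)
  new_window_set(x, meta, fs, config$window_s, recording$channel_names,
                 preprocess_hash(config))
}

#' Normalize windows to per-channel zero mean and unit standard deviation
#'
#' Each channel of each window is standardized independently; a constant
#' channel maps to all zeros. The operation is idempotent up to numerical
#' tolerance.
#'
#' @param ws A `window_set`.
#' @return The normalized `window_set`.
#' @export
normalize_windows <- function(ws) {
  d <- dim(ws$x)
  if (d[3] == 0) return(ws)
  x <- ws$x
  for (j in seq_len(d[3])) {
    m <- x[, , j, drop = FALSE]
    dim(m) <- d[1:2]
    mu <- rowMeans(m)
    m <- m - mu
    s <- sqrt(rowMeans(m^2))
    s[s < 1e-12] <- Inf   # constant channel -> zeros
    x[, , j] <- m / s
  }
  ws$x <- x
  ws
}

#' Balance classes by random under-sampling of the majority class
#'
#' @param ws A `window_set` containing both classes.
#' @param seed Integer seed; the selection is uniformly random and
#'   reproducible.
#' @return A `window_set` with equal class counts; the minority class is
#'   untouched.
#' @export
balance_undersample <- function(ws, seed = 1L) {
  y <- ws$meta$y
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) {
    recs <- paste(unique(ws$meta$record_id), collapse = ", ")
    rlang::abort(sprintf(
      "cannot balance: only one class present (records: %s)", recs),
      class = "seizadapt_error")
  }
  if (n0 == n1) return(ws)
  maj <- if (n0 > n1) 0 else 1
  k <- min(n0, n1)
  maj_idx <- which(y == maj)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, k)))
  keep <- sort(c(which(y != maj), keep_maj))
  subset_windows(ws, keep)
}

#' Stratified train/validation/test split
#'
#' Windows are split class-stratified into disjoint, exhaustive subsets with
#' the given fractions, reproducibly from `seed`.
#'
#' @param ws A `window_set`.
#' @param fractions Length-3 numeric (train, validation, test) summing to 1.
#' @param seed Integer seed.
#' @return A named list of `window_set`s: `train`, `val`, `test`.
#' @export
split_multisubject <- function(ws, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  assert_that(length(fractions) == 3L && abs(sum(fractions) - 1) < 1e-8,
              "`fractions` must be three numbers summing to 1")
  y <- ws$meta$y
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      if (n_tr + n_va > n) n_va <- n - n_tr
      assign[idx[seq_len(n_tr)]] <- 1L
      if (n_va > 0) assign[idx[n_tr + seq_len(n_va)]] <- 2L
      if (n - n_tr - n_va > 0) assign[idx[(n_tr + n_va + 1):n]] <- 3L
    }
  })
  out <- list(train = subset_windows(ws, which(assign == 1L)),
              val = subset_windows(ws, which(assign == 2L)),
              test = subset_windows(ws, which(assign == 3L)))
  empty <- names(out)[vapply(out, n_windows, 0L) == 0L & fractions > 0]
  assert_that(length(empty) == 0L,
              sprintf("split produced empty subset(s): %s",
                      paste(empty, collapse = ", ")))
  out
}

#' Full preprocessing pipeline for a list of recordings
#'
#' filters -> interval labelling -> windowing -> normalization, merged across
#' recordings. Balancing and splitting are left to the caller (they depend on
#' the evaluation protocol).
#'
#' @param recordings List of [new_recording()] objects.
#' @param config A [preprocess_config()].
#' @param filter If `FALSE`, skip the notch/band-pass stage (useful when the
#'   input is already filtered).
#' @return A merged, normalized `window_set`.
#' @export
preprocess_recordings <- function(recordings, config = preprocess_config(),
                                  filter = TRUE) {
  sets <- lapply(recordings, function(rec) {
    assert_that(nrow(rec$data) >= config$min_channels,
                sprintf("recording %s rejected: %d channel(s), minimum is %d",
                        rec$record_id, nrow(rec$data), config$min_channels))
    if (filter) rec <- apply_filters(rec, config)
    iv <- label_intervals(rec, config)
    normalize_windows(extract_windows(rec, iv, config))
  })
  merge_window_sets(sets)
}
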