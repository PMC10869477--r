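dur_rec <- function(duration_s, ann = empty_annotations(), fs = 1) {
  # lightweight recording for interval logic: content is irrelevant
  new_recording("r1", matrix(0, 1, duration_s * fs), fs, "c1",
                annotations = ann)
}

test_that("filters notch the mains line and preserve the pass band", {
  fs <- 256
  t <- seq_len(20 * fs) / fs
  rec <- new_recording("s", rbind(sin(2 * pi * 50 * t),
                                  sin(2 * pi * 10 * t),
                                  rep(5, length(t))),
                       fs, c("a", "b", "c"))
  out <- apply_filters(rec, preprocess_config())
  mid <- seq(2 * fs, 18 * fs)       # keep clear of filtfilt edge transients
  rms <- function(v) sqrt(mean(v^2))
  atten_50 <- 20 * log10(rms(out$data[1, mid]) / rms(rec$data[1, mid]))
  expect_lt(atten_50, -20)
  change_10 <- 20 * log10(rms(out$data[2, mid]) / rms(rec$data[2, mid]))
  expect_lt(abs(change_10), 1)
  # DC sits below the 0.5 Hz cut-on
  expect_lt(max(abs(out$data[3, mid])), 0.05)
  expect_identical(dim(out$data), dim(rec$data))
})

test_that("zero-phase filtering does not shift features in time", {
  fs <- 256
  t <- seq_len(8 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  rec <- new_recording("s", rbind(x), fs, "a")
  out <- apply_filters(rec, preprocess_config())
  mid <- seq(2 * fs, 6 * fs)
  shifts <- -3:3
  cors <- vapply(shifts, function(s) {
    stats::cor(out$data[1, mid + s], x[mid])
  }, 0)
  expect_equal(shifts[which.max(cors)], 0L)
})

test_that("sampling rates too low for the band edge are rejected", {
  rec <- new_recording("s", matrix(0, 1, 128 * 4), 128, "a")
  expect_seiz_error(apply_filters(rec, preprocess_config()), "128")
  rec512 <- new_recording("s", matrix(rnorm(512), 1, 512), 512, "a")
  expect_s3_class(apply_filters(rec512, preprocess_config()),
                  "seiz_recording")
})

test_that("interval labelling implements horizon, exclusion and clipping", {
  cfg <- preprocess_config()   # 1 h pre-ictal horizon, 1 h post-ictal guard

  # one mid-recording seizure
  iv <- label_intervals(dur_rec(8000, tibble::tibble(onset_s = 5000,
                                                     offset_s = 5030)), cfg)
  expect_equal(as.data.frame(iv[, 2:4]), data.frame(
    start_s = c(0, 1400, 5000), end_s = c(1400, 5000, 8000),
    label = c("interictal", "preictal", "excluded")))

  # no seizures: one inter-ictal interval
  iv0 <- label_intervals(dur_rec(1234), cfg)
  expect_equal(as.data.frame(iv0[, 2:4]), data.frame(
    start_s = 0, end_s = 1234, label = "interictal"))

  # early seizure: pre-ictal horizon clipped at the record start
  iv1 <- label_intervals(dur_rec(9000, tibble::tibble(onset_s = 1800,
                                                      offset_s = 1830)), cfg)
  expect_equal(as.data.frame(iv1[, 2:4]), data.frame(
    start_s = c(0, 1800, 5430), end_s = c(1800, 5430, 9000),
    label = c("preictal", "excluded", "interictal")))

  # consecutive seizures: the second pre-ictal horizon is clipped at the
  # first seizure's exclusion end; exclusion beats pre-ictal
  iv2 <- label_intervals(dur_rec(16000, tibble::tibble(
    onset_s = c(5000, 10000), offset_s = c(5030, 10040))), cfg)
  expect_equal(as.data.frame(iv2[, 2:4]), data.frame(
    start_s = c(0, 1400, 5000, 8630, 10000, 13640),
    end_s = c(1400, 5000, 8630, 10000, 13640, 16000),
    label = c("interictal", "preictal", "excluded", "preictal", "excluded",
              "interictal")))
})

test_that("intervals are disjoint, exhaustive and config-sensitive", {
  ann <- tibble::tibble(onset_s = c(900, 2000), offset_s = c(920, 2030))
  cfg <- preprocess_config(preictal_horizon_s = 600,
                           postictal_exclusion_s = 300)
  iv <- label_intervals(dur_rec(4000, ann), cfg)
  expect_equal(iv$start_s[1], 0)
  expect_equal(iv$end_s[nrow(iv)], 4000)
  expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)])  # exhaustive, disjoint
  # post-ictal guard length is honoured
  expect_true(any(iv$label == "excluded" & iv$start_s == 900 &
                    iv$end_s == 920 + 300))
})

test_that("windows tile labeled intervals with the floor rule", {
  fs <- 256
  cfg <- preprocess_config(preictal_horizon_s = 3600, window_s = 10,
                           min_channels = 1)
  # a 3600 s pre-ictal interval yields 360 windows of 2560 samples
  rec <- new_recording("r1", matrix(rnorm(fs * 3610), 1), fs, "c1",
                       annotations = tibble::tibble(onset_s = 3600,
                                                    offset_s = 3610))
  ws <- extract_windows(rec, label_intervals(rec, cfg), cfg)
  pre <- ws$meta$y == 1
  expect_equal(sum(pre), 360L)
  expect_identical(dim(ws$x)[1:2], c(1L, 2560L))
  expect_equal(diff(sort(ws$meta$start_s[pre])), rep(10, 359))

  # 25 s interval -> 2 windows, partial tail discarded
  rec2 <- dur_rec(25, fs = fs)
  ws2 <- extract_windows(rec2, label_intervals(rec2, cfg), cfg)
  expect_equal(n_windows(ws2), 2L)
  expect_equal(ws2$meta$start_s, c(0, 10))

  # window content matches the raw signal slice
  j <- 5
  i0 <- ws$meta$start_s[j] * fs
  expect_identical(ws$x[1, , j], rec$data[1, i0 + 1:2560])
})

test_that("window bookkeeping matches the per-interval floor sum", {
  ann <- tibble::tibble(onset_s = c(50, 130), offset_s = c(55, 136))
  cfg <- preprocess_config(preictal_horizon_s = 30,
                           postictal_exclusion_s = 11, window_s = 4,
                           min_channels = 1)
  rec <- dur_rec(200, ann, fs = 4)
  iv <- label_intervals(rec, cfg)
  ws <- extract_windows(rec, iv, cfg)
  use <- iv[iv$label != "excluded", ]
  expect_equal(n_windows(ws),
               sum(floor((use$end_s - use$start_s) / cfg$window_s)))
  # no window overlaps an excluded interval
  excl <- iv[iv$label == "excluded", ]
  for (j in seq_len(n_windows(ws))) {
    w0 <- ws$meta$start_s[j]
    w1 <- w0 + cfg$window_s
    expect_false(any(w0 < excl$end_s & w1 > excl$start_s))
  }
})

test_that("normalization gives zero mean unit sd per channel, idempotently", {
  x <- array(0, c(2, 4, 2))
  x[1, , 1] <- c(1, 2, 3, 4)
  x[2, , 1] <- c(5, 5, 5, 5)          # constant channel
  x[, , 2] <- rnorm(8)
  ws <- new_window_set(
    x, tibble::tibble(subject_id = "a", record_id = "a", start_s = c(0, 4),
                      y = c(0, 1)),
    fs = 1, window_s = 4, channel_names = c("c1", "c2"))
  nz <- normalize_windows(ws)
  expect_equal(mean(nz$x[1, , 1]), 0, tolerance = 1e-5)
  expect_equal(sqrt(mean(nz$x[1, , 1]^2)), 1, tolerance = 1e-5)
  expect_equal(nz$x[2, , 1], rep(0, 4))
  nz2 <- normalize_windows(nz)
  expect_equal(nz2$x, nz$x, tolerance = 1e-5)
})

test_that("under-sampling balances classes reproducibly", {
  ws <- toy_window_set(n = 140)
  ws_im <- subset_windows(ws, c(which(ws$meta$y == 0),
                                which(ws$meta$y == 1)[1:40]))
  b1 <- balance_undersample(ws_im, seed = 5)
  expect_equal(sum(b1$meta$y == 0), 40L)
  expect_equal(sum(b1$meta$y == 1), 40L)
  # minority untouched
  expect_identical(window_signatures(subset_windows(b1, which(b1$meta$y == 1))),
                   window_signatures(subset_windows(ws_im,
                                                    which(ws_im$meta$y == 1))))
  b2 <- balance_undersample(ws_im, seed = 5)
  expect_identical(b1$x, b2$x)
  b3 <- balance_undersample(ws_im, seed = 6)
  expect_false(identical(b1$meta$start_s, b3$meta$start_s))
  # already balanced -> identity
  bal <- subset_windows(ws, 1:80)
  expect_identical(balance_undersample(bal, 1)$x, bal$x)
  # single class -> error naming records
  one <- subset_windows(ws, which(ws$meta$y == 0))
  expect_seiz_error(balance_undersample(one, 1), "T01")
})

test_that("stratified splits are disjoint, exhaustive and reproducible", {
  ws <- toy_window_set(n = 1000, C = 2, T = 16)
  sp <- split_multisubject(ws, c(0.6, 0.2, 0.2), seed = 3)
  expect_equal(n_windows(sp$train), 600L)
  expect_equal(n_windows(sp$val), 200L)
  expect_equal(n_windows(sp$test), 200L)
  for (part in sp) {
    expect_lte(abs(sum(part$meta$y == 1) - sum(part$meta$y == 0)), 1L)
  }
  sigs <- lapply(sp, window_signatures)
  expect_length(intersect(sigs$train, sigs$val), 0L)
  expect_length(intersect(sigs$train, sigs$test), 0L)
  expect_length(intersect(sigs$val, sigs$test), 0L)
  expect_setequal(unlist(sigs), window_signatures(ws))
  sp2 <- split_multisubject(ws, c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(sp$train$x, sp2$train$x)
  expect_seiz_error(split_multisubject(ws, c(0.5, 0.5)), "three numbers")
  expect_seiz_error(split_multisubject(subset_windows(ws, 1:2),
                                       c(0.9, 0.05, 0.05)), "empty")
})

test_that("the full pipeline is reproducible and rejects thin montages", {
  cc <- desk_cohort_config(n_subjects = 2, n_channels = 3)
  recs <- generate_cohort(cc)
  cfg <- desk_preprocess_config(n_channels = 3)
  ws1 <- preprocess_recordings(recs, cfg)
  ws2 <- preprocess_recordings(recs, cfg)
  expect_identical(ws1$x, ws2$x)
  expect_true(all(abs(apply(ws1$x, c(1, 3), mean)) < 1e-5))
  cfg23 <- desk_preprocess_config(n_channels = 23)
  expect_seiz_error(preprocess_recordings(recs, cfg23), "minimum is 23")
})
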