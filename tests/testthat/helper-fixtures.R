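# Shared fixtures, all generated in code. The cache avoids regenerating the
# same synthetic cohorts across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but realistic desk-scale cohort: 6 subjects, ~100 pre-ictal +
# ~140 inter-ictal one-second windows each, 4 channels at 256 Hz.
desk_cohort_config <- function(shift = 1, master_seed = 1, n_subjects = 6,
                               n_channels = 4) {
  cohort_config(n_subjects = n_subjects, n_channels = n_channels,
                sampling_rate_hz = 256, record_duration_s = 280,
                seizures_per_subject = 1, shift_strength = shift,
                master_seed = master_seed, preictal_span_s = 100,
                ictal_duration_s = 10)
}

desk_preprocess_config <- function(n_channels = 4) {
  preprocess_config(preictal_horizon_s = 100, postictal_exclusion_s = 30,
                    window_s = 1, min_channels = n_channels)
}

desk_windows <- function(shift = 1, master_seed = 1, n_subjects = 6,
                         n_channels = 4) {
  key <- sprintf("cohort_%g_%d_%d_%d", shift, master_seed, n_subjects,
                 n_channels)
  cached(key, {
    cc <- desk_cohort_config(shift, master_seed, n_subjects, n_channels)
    preprocess_recordings(generate_cohort(cc),
                          desk_preprocess_config(n_channels))
  })
}

# Small model matched to the desk-scale windows (1 s @ 256 Hz, 4 channels).
desk_model_config <- function() {
  model_config(C = 4, T = 256, F1 = 4, F2 = 2, F3 = 4, dropout_p = 0.25,
               kernel1 = 64, kernel2 = 32)
}

desk_train_config <- function(..., seed = 1) {
  defaults <- list(max_epochs = 6L, patience_epochs = 4L, batch_size = 64L,
                   seed = seed, disc_hidden = c(32L, 32L))
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

# A tiny configuration for gradient checks and shape plumbing (milliseconds).
tiny_model_config <- function(dropout_p = 0) {
  model_config(C = 3, T = 32, F1 = 2, F2 = 2, F3 = 3, dropout_p = dropout_p,
               pool = 4, kernel1 = 7, kernel2 = 5)
}

# Random labeled windows with a class-dependent narrowband component: class 1
# carries extra 20 Hz power. Linearly separable by band power, cheap to make.
toy_window_set <- function(n = 120, C = 3, T = 32, fs = 32, seed = 1,
                           amp = 2, subject_id = "T01") {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- array(rnorm(C * T * n), c(C, T, n))
    tt <- seq_len(T) / fs
    for (j in which(y == 1)) {
      ph <- runif(1, 0, 2 * pi)
      x[, , j] <- x[, , j] + amp * matrix(rep(sin(2 * pi * 10 * tt + ph),
                                              each = C), C, T)
    }
    new_window_set(
      x, tibble::tibble(subject_id = subject_id, record_id = subject_id,
                        start_s = seq_len(n) - 1, y = y),
      fs = fs, window_s = T / fs, channel_names = sprintf("c%02d", seq_len(C)))
  })
}

# Per-window signature strings for leakage (hash-intersection) checks.
window_signatures <- function(ws) {
  vapply(seq_len(n_windows(ws)), function(j) {
    v <- ws$x[, , j]
    paste(sprintf("%.6e", c(sum(v), sum(v * v), v[1, 1], v[length(v)])),
          collapse = "|")
  }, "")
}

expect_seiz_error <- function(expr, pattern = NULL) {
  expect_error(expr, regexp = pattern, class = "seizadapt_error")
}
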