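#' Subject-level generative parameters for the synthetic cohort
#'
#' Each synthetic subject is characterized by an alpha-like background
#' oscillation at a subject-specific peak frequency, a band-limited component
#' whose power is multiplied during pre-ictal intervals (the class signal), a
#' subject-specific channel mixing matrix, and additive sensor noise. Between-
#' subject dispersion of these parameters is what produces the domain shift
#' that cross-subject classifiers must survive.
#'
#' @param subject_id Character scalar.
#' @param mixing_matrix_seed Integer seed for the subject's mixing matrix.
#' @param background_peak_hz Centre of the subject's background oscillation,
#'   conventionally in the 8-13 Hz alpha band.
#' @param background_gain Positive amplitude of the background oscillation
#'   relative to the pink-noise floor (unit sd).
#' @param preictal_band Length-2 numeric, (low, high) Hz of the band whose
#'   power changes before seizures. Must lie inside (0.5, 70) so the class
#'   signal survives the analysis band-pass.
#' @param preictal_gain Positive amplitude multiplier applied to all
#'   `preictal_band` content during pre-ictal intervals; band power is
#'   multiplied by `preictal_gain^2`. Must differ from 1 for the classes to be
#'   separable.
#' @param noise_sd Positive standard deviation of additive white sensor noise.
#' @param mixing_blend Scalar in `[0, 1]`: 0 means the subject uses the
#'   cohort-shared mixing matrix, 1 a fully subject-specific one.
#' @param shared_mixing_seed Integer seed of the cohort-shared mixing matrix.
#'
#' @return A `subject_params` list.
#' @export
subject_params <- function(subject_id,
                           mixing_matrix_seed,
                           background_peak_hz = 10.5,
                           background_gain = 2,
                           preictal_band = c(16, 24),
                           preictal_gain = 2.5,
                           noise_sd = 1,
                           mixing_blend = 1,
                           shared_mixing_seed = 1L) {
  assert_that(is_scalar_num(background_peak_hz) && background_peak_hz > 0.5 &&
                background_peak_hz < 70,
              "`background_peak_hz` must lie in (0.5, 70)")
  assert_that(is_scalar_num(background_gain) && background_gain > 0,
              "`background_gain` must be positive")
  assert_that(length(preictal_band) == 2L &&
                preictal_band[1] < preictal_band[2] &&
                preictal_band[1] > 0.5 && preictal_band[2] < 70,
              "`preictal_band` must satisfy 0.5 < low < high < 70")
  assert_that(is_scalar_num(preictal_gain) && preictal_gain > 0,
              "`preictal_gain` must be positive")
  assert_that(is_scalar_num(noise_sd) && noise_sd > 0,
              "`noise_sd` must be positive")
  assert_that(is_scalar_num(mixing_blend) && mixing_blend >= 0 &&
                mixing_blend <= 1, "`mixing_blend` must be in [0, 1]")
  structure(
    list(subject_id = as.character(subject_id),
         mixing_matrix_seed = as.integer(mixing_matrix_seed),
         background_peak_hz = background_peak_hz,
         background_gain = background_gain,
         preictal_band = as.numeric(preictal_band),
         preictal_gain = preictal_gain,
         noise_sd = noise_sd,
         mixing_blend = mixing_blend,
         shared_mixing_seed = as.integer(shared_mixing_seed)),
    class = "subject_params"
  )
}

#' Cohort-level configuration for the synthetic generator
#'
#' @param n_subjects Number of subjects (>= 2; cross-subject protocols are
#'   undefined below that).
#' @param n_channels Electrode count (default 23, the usual 10-20 scalp
#'   montage size).
#' @param sampling_rate_hz Sampling rate, 256 or 512 Hz.
#' @param record_duration_s Length of each subject's recording in seconds.
#' @param seizures_per_subject Seizure count per recording (>= 0).
#' @param shift_strength Scalar in `[0, 1]` scaling between-subject parameter
#'   dispersion; 0 yields identically distributed subjects.
#' @param master_seed Integer master seed. Per-subject seeds are derived from
#'   it by subject index, so adding a subject never changes earlier subjects.
#' @param preictal_span_s Pre-seizure span the generator reserves per seizure
#'   when placing onsets (seconds).
#' @param ictal_duration_s Duration of each generated seizure burst (seconds).
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects,
                          n_channels = 23,
                          sampling_rate_hz = 256,
                          record_duration_s = 14400,
                          seizures_per_subject = 2,
                          shift_strength = 1,
                          master_seed = 1L,
                          preictal_span_s = 3600,
                          ictal_duration_s = 20) {
  assert_that(is_count(n_subjects, min = 2L),
              "`n_subjects` must be an integer >= 2 (cross-subject protocols are undefined otherwise)")
  assert_that(is_count(n_channels), "`n_channels` must be a positive integer")
  assert_that(sampling_rate_hz %in% c(256, 512),
              "`sampling_rate_hz` must be 256 or 512")
  assert_that(is_scalar_num(record_duration_s) && record_duration_s > 0,
              "`record_duration_s` must be positive")
  assert_that(is_count(seizures_per_subject, min = 0L),
              "`seizures_per_subject` must be a non-negative integer")
  assert_that(is_scalar_num(shift_strength) && shift_strength >= 0 &&
                shift_strength <= 1, "`shift_strength` must be in [0, 1]")
  if (seizures_per_subject > 0) {
    need <- seizures_per_subject * (preictal_span_s + ictal_duration_s)
    assert_that(record_duration_s > need,
                sprintf(paste0("record_duration_s = %g cannot contain %d ",
                               "seizure(s) with non-overlapping %g s pre-ictal",
                               " spans (need > %g s)"),
                        record_duration_s, seizures_per_subject,
                        preictal_span_s, need))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_channels = as.integer(n_channels),
         sampling_rate_hz = as.integer(sampling_rate_hz),
         record_duration_s = record_duration_s,
         seizures_per_subject = as.integer(seizures_per_subject),
         shift_strength = shift_strength,
         master_seed = as.integer(master_seed),
         preictal_span_s = preictal_span_s,
         ictal_duration_s = ictal_duration_s),
    class = "cohort_config"
  )
}

# Pink (1/f) noise of length n, unit variance, via spectral shaping.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # two-sided frequency index
  scale <- c(0, 1 / sqrt(f[-1])) # kill DC, shape the rest
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited Gaussian noise of length n, unit variance, ideal FFT mask.
bandlimited_noise <- function(n, fs, low, high) {
  x <- stats::rnorm(n)
  bandpass_fft(x, fs, low, high, renorm = TRUE)
}

# Ideal band-pass by FFT masking. With renorm = TRUE the output is scaled to
# unit sd (used for source synthesis); otherwise the true in-band component is
# returned (used for pre-ictal band scaling).
bandpass_fft <- function(x, fs, low, high, renorm = FALSE) {
  n <- length(x)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  X[f < low | f > high] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  if (renorm) y <- y / stats::sd(y)
  y
}

# Orthonormal mixing matrix from a seed (QR of a Gaussian matrix).
random_orthonormal <- function(n, seed) {
  with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  })
}

# Subject mixing matrix: orthonormalized blend between the cohort-shared
# matrix and a subject-specific one, controlled by mixing_blend.
subject_mixing_matrix <- function(params, n_channels) {
  a_shared <- random_orthonormal(n_channels, params$shared_mixing_seed)
  if (params$mixing_blend == 0) return(a_shared)
  a_own <- random_orthonormal(n_channels, params$mixing_matrix_seed)
  b <- params$mixing_blend
  qr.Q(qr((1 - b) * a_shared + b * a_own))
}

# Deterministic seizure placement: onsets spaced so each seizure's pre-ictal
# span never overlaps the previous seizure, with the remaining (inter-ictal)
# slack spread evenly.
place_seizures <- function(duration_s, n_seizures, preictal_span_s,
                           ictal_duration_s) {
  if (n_seizures == 0) return(empty_annotations())
  block <- preictal_span_s + ictal_duration_s
  slack <- duration_s - n_seizures * block
  assert_that(slack > 0, "recording too short for the configured seizures")
  gap <- slack / (n_seizures + 1)
  j <- seq_len(n_seizures)
  onset <- j * gap + (j - 1) * block + preictal_span_s
  tibble::tibble(onset_s = onset, offset_s = onset + ictal_duration_s)
}

#' Generate one subject's synthetic EEG-like recording
#'
#' The signal is a sum of per-channel pink background noise, a subject-
#' specific narrow-band oscillation at `background_peak_hz`, and a band-
#' limited component in `preictal_band`, mixed across channels by the
#' subject's orthonormal mixing matrix, plus white sensor noise. During each
#' pre-ictal span (the `preictal_span_s` seconds before an annotated onset)
#' the in-band content of every channel is multiplied by `preictal_gain`, so
#' band power rises by `preictal_gain^2` — the ground-truth class signal.
#' Annotated ictal intervals carry an additional high-amplitude broadband
#' burst so downstream exclusion logic has something to exclude.
#'
#' @param params A [subject_params()] object.
#' @param duration_s Recording length in seconds (> 0).
#' @param fs Sampling rate, 256 or 512 Hz.
#' @param seed Integer seed; the output is a pure function of
#'   `(params, duration_s, fs, seed, ...)`.
#' @param n_channels Electrode count.
#' @param n_seizures Number of seizures to embed.
#' @param preictal_span_s Pre-ictal span per seizure in seconds.
#' @param ictal_duration_s Seizure burst duration in seconds.
#'
#' @return A [new_recording()] object with ground-truth annotations.
#' @export
generate_subject_recording <- function(params, duration_s, fs, seed,
                                       n_channels = 23,
                                       n_seizures = 0,
                                       preictal_span_s = 3600,
                                       ictal_duration_s = 20) {
  assert_that(inherits(params, "subject_params"),
              "`params` must come from subject_params()")
  assert_that(is_scalar_num(duration_s) && duration_s > 0,
              "`duration_s` must be positive")
  assert_that(fs %in% c(256, 512),
              sprintf("unsupported sampling rate %s Hz: use 256 or 512", fs))
  n <- as.integer(round(duration_s * fs))
  ann <- place_seizures(duration_s, n_seizures, preictal_span_s,
                        ictal_duration_s)

  x <- with_seed(seed, {
    src <- matrix(0, n_channels, n)
    for (c in seq_len(n_channels)) src[c, ] <- pink_noise(n)
    # Narrow-band background oscillation on source 1 (alpha-like peak).
    pk <- params$background_peak_hz
    src[1, ] <- src[1, ] + params$background_gain *
      bandlimited_noise(n, fs, pk - 1, pk + 1)
    # Always-on band-limited component in the pre-ictal band on source 2.
    src[2, ] <- src[2, ] +
      bandlimited_noise(n, fs, params$preictal_band[1],
                        params$preictal_band[2])
    a <- subject_mixing_matrix(params, n_channels)
    out <- a %*% src
    out <- out + params$noise_sd * matrix(stats::rnorm(n_channels * n),
                                          n_channels, n)
    # Pre-ictal band-power modulation: scale the in-band component of the
    # whole signal (background + noise included) so that in-band power is
    # multiplied by exactly preictal_gain^2 in expectation.
    if (nrow(ann) > 0 && params$preictal_gain != 1) {
      pre_mask <- rep(FALSE, n)
      t_axis <- (seq_len(n) - 1) / fs
      for (j in seq_len(nrow(ann))) {
        lo <- max(0, ann$onset_s[j] - preictal_span_s)
        pre_mask <- pre_mask | (t_axis >= lo & t_axis < ann$onset_s[j])
      }
      if (any(pre_mask)) {
        g <- params$preictal_gain
        for (c in seq_len(n_channels)) {
          xb <- bandpass_fft(out[c, ], fs, params$preictal_band[1],
                             params$preictal_band[2])
          out[c, pre_mask] <- out[c, pre_mask] + (g - 1) * xb[pre_mask]
        }
      }
      # Ictal bursts: short high-amplitude broadband activity.
      for (j in seq_len(nrow(ann))) {
        idx <- which(t_axis >= ann$onset_s[j] & t_axis < ann$offset_s[j])
        if (length(idx)) {
          out[, idx] <- out[, idx] +
            5 * matrix(stats::rnorm(n_channels * length(idx)),
                       n_channels, length(idx))
        }
      }
    }
    out * 25  # microvolt-like scale
  })

  new_recording(subject_id = params$subject_id, data = x, fs = fs,
                channel_names = sprintf("EEG%02d", seq_len(n_channels)),
                annotations = ann)
}

# Draw one subject's parameters. Dispersion scales with shift_strength; at 0
# every subject gets the centre values (identical params, distinct seeds).
draw_subject_params <- function(config, i) {
  s <- config$shift_strength
  seed_i <- derive_seed(config$master_seed, i)
  with_seed(seed_i, {
    u <- stats::runif(6, -1, 1)
    low <- 16 + s * 6 * u[3]
    high <- 24 + s * 6 * u[4]
    if (high - low < 4) { mid <- (low + high) / 2; low <- mid - 2; high <- mid + 2 }
    low <- max(low, 1); high <- min(high, 65)
    subject_params(
      subject_id = sprintf("S%02d", i),
      mixing_matrix_seed = derive_seed(config$master_seed, 10000L + i),
      background_peak_hz = 10.5 + s * 2.5 * u[1],
      background_gain = 2 * exp(s * 0.7 * u[2]),
      preictal_band = c(low, high),
      preictal_gain = 2.5 * exp(s * 0.2 * u[5]),
      noise_sd = exp(s * 0.5 * u[6]),
      mixing_blend = s,
      shared_mixing_seed = derive_seed(config$master_seed, 99991L)
    )
  })
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws per-subject generative parameters with dispersion proportional to
#' `shift_strength` (0 gives identically distributed subjects: identical
#' parameters, distinct seeds) and synthesizes one recording per subject.
#' Per-subject seeds are derived from `master_seed` by subject index, so
#' regenerating with more subjects reproduces earlier subjects bit-for-bit.
#'
#' @param config A [cohort_config()] object.
#'
#' @return A list of [new_recording()] objects, one per subject.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "`config` must come from cohort_config()")
  lapply(seq_len(config$n_subjects), function(i) {
    params <- draw_subject_params(config, i)
    generate_subject_recording(
      params,
      duration_s = config$record_duration_s,
      fs = config$sampling_rate_hz,
      seed = derive_seed(config$master_seed, 20000L + i),
      n_channels = config$n_channels,
      n_seizures = config$seizures_per_subject,
      preictal_span_s = config$preictal_span_s,
      ictal_duration_s = config$ictal_duration_s
    )
  })
}
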