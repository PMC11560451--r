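#' Specification for a synthetic EEG recording
#'
#' Describes one synthetic multichannel scalp EEG recording in the style of a
#' pediatric long-term monitoring record: 22 bipolar channels at 256 Hz,
#' pink-ish (1/f power) interictal background with weak inter-channel
#' correlation, and annotated ictal intervals during which a frequency-jittered
#' rhythmic oscillation with elevated cross-channel synchrony is superimposed,
#' strongest on a focal channel subset.
#'
#' `ictal_gain` multiplies seizure amplitude: the common rhythm is added with
#' per-channel amplitude `(ictal_gain - 1)` times the background scale (focal
#' channels at full strength, others at half), so `ictal_gain = 1` together with
#' `ictal_sync = background_corr` degenerates to a recording whose ictal and
#' interictal stretches are statistically indistinguishable.
#'
#' @param duration_s Record length in seconds.
#' @param seizure_intervals List of `c(onset_s, offset_s)` pairs; half-open
#'   `[onset, offset)`, disjoint, inside `[0, duration_s]`.
#' @param n_channels Number of channels (default 22, the canonical montage).
#' @param fs Sampling rate in Hz (default 256).
#' @param background_corr Inter-channel correlation of the interictal
#'   background, in `[0, 1)`.
#' @param ictal_freq_hz Center frequency of the seizure rhythm, in `[3, 12]` Hz.
#' @param ictal_sync Cross-channel synchrony during seizures, in
#'   `[background_corr, 1]`.
#' @param ictal_gain Seizure amplitude multiplier, `>= 1`.
#' @param focal_channels Indices of channels carrying the strongest rhythm.
#' @param patient_id Label.
#' @param seed Integer; same spec + same seed gives bit-identical output.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(duration_s,
                       seizure_intervals = list(),
                       n_channels = 22L, fs = 256,
                       background_corr = 0.15,
                       ictal_freq_hz = 6,
                       ictal_sync = 0.8,
                       ictal_gain = 3,
                       focal_channels = 1:6,
                       patient_id = "P01",
                       seed = 1L) {
  spec <- list(n_channels = as.integer(n_channels), fs = fs,
               duration_s = duration_s,
               seizure_intervals = seizure_intervals,
               background_corr = background_corr,
               ictal_freq_hz = ictal_freq_hz,
               ictal_sync = ictal_sync, ictal_gain = ictal_gain,
               focal_channels = as.integer(focal_channels),
               patient_id = patient_id, seed = as.integer(seed))
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  abort_if(!is_count(spec$n_channels), "n_channels must be a positive count")
  abort_if(!is_scalar(spec$fs) || spec$fs <= 0, "fs must be positive")
  abort_if(!is_scalar(spec$duration_s) || spec$duration_s <= 0,
           "duration_s must be positive")
  abort_if(!is_scalar(spec$background_corr) || spec$background_corr < 0 ||
             spec$background_corr >= 1, "background_corr must be in [0, 1)")
  abort_if(!is_scalar(spec$ictal_freq_hz) || spec$ictal_freq_hz < 3 ||
             spec$ictal_freq_hz > 12, "ictal_freq_hz must be in [3, 12]")
  abort_if(!is_scalar(spec$ictal_sync) || spec$ictal_sync < spec$background_corr ||
             spec$ictal_sync > 1,
           "ictal_sync must be in [background_corr, 1]")
  abort_if(!is_scalar(spec$ictal_gain) || spec$ictal_gain < 1,
           "ictal_gain must be >= 1")
  abort_if(any(spec$focal_channels < 1 | spec$focal_channels > spec$n_channels),
           "focal_channels out of range")
  iv <- spec$seizure_intervals
  if (length(iv)) {
    m <- do.call(rbind, lapply(iv, function(x) {
      abort_if(length(x) != 2L || !is.numeric(x), "each seizure interval must be c(onset, offset)")
      x
    }))
    abort_if(any(m[, 2L] <= m[, 1L]), "seizure offset must exceed onset")
    abort_if(any(m[, 1L] < 0) || any(m[, 2L] > spec$duration_s),
             "seizure intervals must lie within [0, duration_s]")
    o <- order(m[, 1L])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1L)
      abort_if(any(m[-1L, 1L] < m[-nrow(m), 2L]), "seizure intervals must be disjoint")
  }
  invisible(spec)
}

# 1/f-power ("pink-ish") noise via spectral shaping; unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                # avoid DC blow-up
  f <- pmin(f, n - f + 1)                  # symmetric frequency index
  sp <- sp * f^(-0.5)                      # amplitude ~ f^-1/2 => power ~ 1/f
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic EEG recording
#'
#' Interictal samples are per-channel 1/f-shaped noise mixed with a shared
#' 1/f component: `x_i = sqrt(1 - w) e_i + sqrt(w) c` with `w = background_corr`,
#' so the expected pairwise Pearson correlation equals `background_corr`.
#' Inside seizure intervals the mixing weight rises to `ictal_sync` and a
#' common sinusoid at `ictal_freq_hz` (random phase per seizure, +/-10%
#' frequency jitter, per-channel gain highest on `focal_channels`) is added
#' with amplitude `(ictal_gain - 1)` relative to the background scale, raising
#' both variance and pairwise correlation of ictal stretches.
#'
#' @param spec A [synth_spec()].
#' @return An `eeg_recording`: list with `signal` (channels x samples, nominal
#'   microvolts), `fs`, `channel_names`, `seizure_intervals`, `patient_id`.
#' @examples
#' rec <- generate_recording(synth_spec(duration_s = 30,
#'   seizure_intervals = list(c(10, 20)), seed = 7))
#' dim(rec$signal)
#' @export
generate_recording <- function(spec) {
  validate_synth_spec(spec)
  n <- spec$n_channels
  ns <- round(spec$duration_s * spec$fs)
  ch_names <- if (n == 22L) canonical_channels() else sprintf("CH%02d", seq_len(n))
  with_seed(spec$seed, {
    shared <- pink_noise(ns)
    E <- matrix(0, n, ns)
    for (i in seq_len(n)) E[i, ] <- pink_noise(ns)
    w <- rep(spec$background_corr, ns)
    ict <- sample_labels_from_intervals(spec$seizure_intervals, spec$fs, ns)
    w[ict == 1L] <- spec$ictal_sync
    X <- sqrt(1 - rep(w, each = n)) * E +
      outer(rep(1, n), sqrt(w) * shared)
    amp <- (spec$ictal_gain - 1) * ifelse(seq_len(n) %in% spec$focal_channels, 1, 0.5)
    if (spec$ictal_gain > 1) {
      for (iv in spec$seizure_intervals) {
        i0 <- floor(iv[1L] * spec$fs) + 1L
        i1 <- min(ceiling(iv[2L] * spec$fs), ns)
        idx <- i0:i1
        tt <- (idx - 1) / spec$fs
        phi <- stats::runif(1, 0, 2 * pi)
        phi_fm <- stats::runif(1, 0, 2 * pi)
        # +/-10% frequency jitter via slow sinusoidal modulation
        finst <- spec$ictal_freq_hz * (1 + 0.1 * sin(2 * pi * 0.3 * tt + phi_fm))
        phase <- 2 * pi * cumsum(finst) / spec$fs + phi
        rhythm <- sin(phase)
        # quarter-second raised-cosine ramps at onset/offset
        ramp <- rep(1, length(idx))
        nr <- min(length(idx) %/% 2L, round(0.25 * spec$fs))
        if (nr > 1L) {
          up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
          ramp[seq_len(nr)] <- up
          ramp[length(ramp) - seq_len(nr) + 1L] <- up
        }
        X[, idx] <- X[, idx] + outer(amp, rhythm * ramp)
      }
    }
    X <- X * 30   # nominal microvolt scale; amplitude units are arbitrary
    rownames(X) <- ch_names
    new_eeg_recording(X, spec$fs, ch_names, spec$seizure_intervals, spec$patient_id)
  })
}

new_eeg_recording <- function(signal, fs, channel_names, seizure_intervals,
                              patient_id) {
  abort_if(nrow(signal) != length(channel_names),
           "channel_names length must equal signal row count")
  abort_if(fs <= 0, "fs must be positive")
  dur <- ncol(signal) / fs
  for (iv in seizure_intervals)
    abort_if(iv[1L] < 0 || iv[2L] > dur + 1e-9, "interval outside record duration")
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 seizure_intervals = seizure_intervals, patient_id = patient_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d ch x %.1f s @ %g Hz, %d seizure(s)\n",
              x$patient_id, nrow(x$signal), ncol(x$signal) / x$fs, x$fs,
              length(x$seizure_intervals)))
  invisible(x)
}

sample_labels_from_intervals <- function(intervals, fs, ns) {
  lab <- integer(ns)
  for (iv in intervals) {
    i0 <- floor(iv[1L] * fs) + 1L
    i1 <- min(ceiling(iv[2L] * fs), ns)   # half-open [onset, offset)
    if (i1 >= i0) lab[i0:i1] <- 1L
  }
  lab
}

#' Per-sample ictal labels of a recording
#'
#' @param rec An `eeg_recording`.
#' @return Integer vector (1 = ictal, 0 = interictal), one entry per sample.
#' @export
sample_labels <- function(rec) {
  sample_labels_from_intervals(rec$seizure_intervals, rec$fs, ncol(rec$signal))
}

#' Generate a cohort of synthetic patients
#'
#' Each patient perturbs the base recording parameters: seizure frequency and
#' gain are scaled by `1 + variability * U(-1, 1)` (clamped to their valid
#' ranges) and, when `variability > 0`, the focal channel subset is redrawn.
#' Noise realizations always differ across patients; with `variability = 0` the
#' parameters are shared exactly.
#'
#' @param n_patients Number of patients (>= 2).
#' @param base A [synth_spec()] serving as the template.
#' @param variability Nonnegative scalar relative perturbation.
#' @param seed Integer master seed; per-patient seeds are derived from it.
#' @return List of `eeg_recording`s with distinct `patient_id`s.
#' @export
generate_cohort <- function(n_patients, base, variability = 0.15, seed = 1L) {
  abort_if(!is_count(n_patients) || n_patients < 2L, "n_patients must be >= 2")
  abort_if(!is_scalar(variability) || variability < 0,
           "variability must be nonnegative")
  validate_synth_spec(base)
  lapply(seq_len(n_patients), function(p) {
    ps <- derive_seed(seed, "cohort-patient", p)
    spec <- base
    with_seed(ps, {
      spec$ictal_freq_hz <- min(12, max(3, base$ictal_freq_hz *
                                          (1 + variability * stats::runif(1, -1, 1))))
      spec$ictal_gain <- max(1, base$ictal_gain *
                               (1 + variability * stats::runif(1, -1, 1)))
      if (variability > 0)
        spec$focal_channels <- sort(sample(base$n_channels,
                                           length(base$focal_channels)))
    })
    spec$patient_id <- sprintf("%s%02d", sub("[0-9]+$", "", base$patient_id), p)
    spec$seed <- derive_seed(ps, "recording-noise")
    generate_recording(spec)
  })
}
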