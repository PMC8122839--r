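# Synthetic ear-EEG generator: background spectrum shaping, steady-state and
# event-related components, and transient artifacts with a ground-truth log.
# All component-adding operations are purely additive, so they commute and
# the simulated recording decomposes exactly into its ingredients.

#' Simulate multichannel background EEG
#'
#' Generates background activity with the statistical structure ear-EEG
#' analyses assume: a 1/f^exponent broadband spectrum (spectral shaping of
#' white noise with seeded random phases), a narrowband alpha rhythm and a
#' power-line component. Channels are distinct realizations that share a
#' configurable common-source fraction.
#'
#' @param duration_s recording duration in seconds.
#' @param fs sampling rate in Hz.
#' @param n_channels number of exploring channels.
#' @param one_over_f_exponent spectral exponent of the broadband background
#'   (power falls as `1/f^exponent`). Default 1.
#' @param broadband_rms RMS of the broadband component per channel, microvolts.
#' @param alpha_freq,alpha_rms alpha-rhythm frequency (Hz) and RMS (uV);
#'   `alpha_rms = 0` disables it.
#' @param line_freq,line_rms power-line frequency (Hz) and RMS (uV);
#'   `line_rms = 0` disables it.
#' @param common_fraction fraction (0-1) of the broadband component shared by
#'   all channels, emulating a common cortical source seen by nearby
#'   electrodes. Default 0.3.
#' @param seed integer seed.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' bg <- simulate_background(duration_s = 2, fs = 500, n_channels = 3, seed = 1)
simulate_background <- function(duration_s, fs, n_channels = 3L,
                                one_over_f_exponent = 1,
                                broadband_rms = 20,
                                alpha_freq = 10, alpha_rms = 5,
                                line_freq = 60, line_rms = 2,
                                common_fraction = 0.3,
                                seed = 1L) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(fs, "fs")
  check_positive_scalar(n_channels, "n_channels")
  check_nonneg_scalar(one_over_f_exponent, "one_over_f_exponent")
  check_nonneg_scalar(broadband_rms, "broadband_rms")
  check_nonneg_scalar(alpha_rms, "alpha_rms")
  check_nonneg_scalar(line_rms, "line_rms")
  if (common_fraction < 0 || common_fraction > 1) {
    stop("`common_fraction` must lie in [0, 1].", call. = FALSE)
  }
  n <- round(duration_s * fs)
  with_seed(seed, {
    common <- pink_noise(n, fs, one_over_f_exponent)
    data <- matrix(0, nrow = n_channels, ncol = n)
    t <- (seq_len(n) - 1L) / fs
    for (ch in seq_len(n_channels)) {
      indep <- pink_noise(n, fs, one_over_f_exponent)
      bb <- sqrt(common_fraction) * common + sqrt(1 - common_fraction) * indep
      x <- broadband_rms * bb
      if (alpha_rms > 0) {
        # slow amplitude waxing/waning typical of alpha bursts
        am <- 1 + 0.5 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
        a <- sin(2 * pi * alpha_freq * t + stats::runif(1, 0, 2 * pi)) * am
        x <- x + alpha_rms * a / sqrt(mean(a^2))
      }
      if (line_rms > 0) {
        x <- x + line_rms * sqrt(2) *
          sin(2 * pi * line_freq * t + stats::runif(1, 0, 2 * pi))
      }
      data[ch, ] <- x
    }
    eeg_recording(data, fs)
  })
}

# Unit-RMS noise restricted to `band` (Hz) by FFT masking of white noise.
band_noise <- function(n, fs, band) {
  X <- stats::fft(stats::rnorm(n))
  freqs <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]
  X[freqs < band[1] | freqs > band[2]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Unit-RMS 1/f^exponent noise by spectral shaping of white noise.
pink_noise <- function(n, fs, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white / sqrt(mean(white^2)))
  X <- stats::fft(white)
  freqs <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]  # fold to physical freq
  gain <- numeric(n)
  nz <- freqs > 0
  gain[nz] <- freqs[nz]^(-exponent / 2)
  x <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Add a steady-state response component
#'
#' Adds a sinusoid phase-locked at the modulation frequency `fm` (plus
#' optional harmonics) to every channel, emulating the auditory steady-state
#' response whose spectral peak sits at `fm` and possibly its harmonics.
#'
#' @param rec an [eeg_recording()].
#' @param fm modulation frequency in Hz.
#' @param amplitude_uv peak amplitude at `fm`, microvolts.
#' @param harmonic_amplitudes optional numeric vector of peak amplitudes for
#'   harmonics `2*fm, 3*fm, ...` (uV).
#' @param phase phase offset in radians at `fm`.
#' @return A new [eeg_recording()]; the input is not modified.
#' @export
add_assr_component <- function(rec, fm, amplitude_uv,
                               harmonic_amplitudes = numeric(0),
                               phase = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_positive_scalar(fm, "fm")
  check_nonneg_scalar(amplitude_uv, "amplitude_uv")
  if (fm >= rec$fs / 2) {
    stop("`fm` must lie below the Nyquist frequency.", call. = FALSE)
  }
  amps <- c(amplitude_uv, harmonic_amplitudes)
  freqs <- fm * seq_along(amps)
  if (any(freqs >= rec$fs / 2 & amps > 0)) {
    stop("a harmonic with nonzero amplitude lies at or above Nyquist.",
         call. = FALSE)
  }
  t <- (seq_len(n_samples(rec)) - 1L) / rec$fs
  comp <- numeric(length(t))
  for (k in seq_along(amps)) {
    if (amps[k] > 0) comp <- comp + amps[k] * sin(2 * pi * freqs[k] * t + k * phase)
  }
  data <- sweep(rec$data, 2L, comp, "+")
  eeg_recording(data, rec$fs, rec$channel_labels, rec$schedule)
}

#' ERP component template
#'
#' A Gaussian-shaped stimulus-locked deflection: peak at `latency_ms` after
#' stimulus onset, temporal spread `width_ms` (Gaussian SD) and signed peak
#' `amplitude_uv`. `label` selects which scheduled events receive it
#' (`"target"`, `"standard"`, or `"all"`).
#'
#' @param label condition the template applies to.
#' @param latency_ms peak latency after onset, milliseconds.
#' @param width_ms Gaussian SD, milliseconds; must be positive.
#' @param amplitude_uv signed peak amplitude, microvolts.
#' @return A one-row tibble usable in [add_erp_components()].
#' @export
erp_template <- function(label, latency_ms, width_ms, amplitude_uv) {
  check_positive_scalar(width_ms, "width_ms")
  tibble::tibble(label = label, latency_ms = latency_ms,
                 width_ms = width_ms, amplitude_uv = amplitude_uv)
}

#' Add stimulus-locked ERP components
#'
#' For each scheduled event matching a template's label, adds a Gaussian
#' deflection peaking `latency_ms` (plus seeded Gaussian jitter) after the
#' event onset. Events whose template tail would extend beyond the recording
#' are skipped with a warning.
#'
#' @param rec an [eeg_recording()].
#' @param schedule event schedule tibble (`onset_s`, `label`, `sequence`).
#' @param templates tibble of templates, e.g. rows from [erp_template()].
#' @param jitter_ms SD of the per-event latency jitter, milliseconds.
#' @param channel_gains per-channel projection gains of the ERP sources
#'   (cortical ERP generators project with electrode-dependent strength, and
#'   with a topography distinct from ocular artifacts); `NULL` (default)
#'   means uniform gain 1. Gains should average 1 so the channel-mean ERP
#'   equals the template.
#' @param seed integer seed for the jitter.
#' @return A new [eeg_recording()] carrying `schedule`.
#' @export
add_erp_components <- function(rec, schedule, templates, jitter_ms = 0,
                               channel_gains = NULL, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  schedule <- validate_schedule(schedule)
  templates <- tibble::as_tibble(templates)
  check_nonneg_scalar(jitter_ms, "jitter_ms")
  n <- n_samples(rec)
  t <- (seq_len(n) - 1L) / rec$fs
  add <- numeric(n)
  n_skipped <- 0L
  with_seed(seed, {
    for (i in seq_len(nrow(templates))) {
      tpl <- templates[i, ]
      events <- if (tpl$label == "all") schedule else
        schedule[schedule$label == tpl$label, ]
      for (onset in events$onset_s) {
        jit <- if (jitter_ms > 0) stats::rnorm(1, 0, jitter_ms / 1000) else 0
        peak_t <- onset + tpl$latency_ms / 1000 + jit
        sd_s <- tpl$width_ms / 1000
        if (peak_t + 4 * sd_s > n / rec$fs) {
          n_skipped <- n_skipped + 1L
          next
        }
        lo <- max(1L, onset_to_sample(peak_t - 5 * sd_s, rec$fs) + 1L)
        hi <- min(n, onset_to_sample(peak_t + 5 * sd_s, rec$fs) + 1L)
        idx <- lo:hi
        add[idx] <- add[idx] +
          tpl$amplitude_uv * exp(-((t[idx] - peak_t)^2) / (2 * sd_s^2))
      }
    }
  })
  if (n_skipped > 0L) {
    warning(sprintf("%d event(s) extended beyond the recording and were skipped.",
                    n_skipped), call. = FALSE)
  }
  if (is.null(channel_gains)) channel_gains <- rep(1, n_channels(rec))
  stopifnot(length(channel_gains) == n_channels(rec))
  data <- rec$data + outer(channel_gains, add)
  eeg_recording(data, rec$fs, rec$channel_labels, schedule)
}

#' Add blink and muscle artifacts
#'
#' Inserts eye-blink transients (large, low-frequency, squared-sine-shaped,
#' projected onto all channels through a fixed mixing vector dominated by the
#' frontal-most channel) and short band-limited muscle bursts at seeded
#' Poisson rates, and returns a log of every inserted artifact so downstream
#' rejection can be scored against ground truth.
#'
#' @param rec an [eeg_recording()].
#' @param blink_rate_per_min,blink_amplitude_uv,blink_width_ms blink Poisson
#'   rate, peak amplitude on the frontal-most channel (uV) and full width (ms).
#' @param muscle_rate_per_min,muscle_band,muscle_rms_uv muscle-burst rate,
#'   frequency band (Hz, length-2) and within-burst RMS (uV).
#' @param muscle_width_ms burst duration, milliseconds.
#' @param blink_mixing per-channel projection weights of the blink source;
#'   defaults to a signed frontal-dominant profile (with a referenced ear
#'   montage the ocular dipole projects with opposite polarity on
#'   derivations on either side of its zero line), which keeps the blink
#'   topography distinct from the all-positive ERP topography.
#' @param seed integer seed.
#' @return A list with elements `recording` (new [eeg_recording()]) and
#'   `log` (tibble: `kind`, `onset_s`, `peak_s`, `width_ms`, `amplitude_uv`).
#' @export
add_artifacts <- function(rec,
                          blink_rate_per_min = 2,
                          blink_amplitude_uv = 200,
                          blink_width_ms = 250,
                          muscle_rate_per_min = 1,
                          muscle_band = c(20, 45),
                          muscle_rms_uv = 30,
                          muscle_width_ms = 500,
                          blink_mixing = NULL,
                          seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_nonneg_scalar(blink_rate_per_min, "blink_rate_per_min")
  check_nonneg_scalar(muscle_rate_per_min, "muscle_rate_per_min")
  nch <- n_channels(rec)
  n <- n_samples(rec)
  dur_min <- rec_duration(rec) / 60
  if (is.null(blink_mixing)) {
    blink_mixing <- seq(1, -0.4, length.out = nch)
  }
  stopifnot(length(blink_mixing) == nch)
  data <- rec$data
  log <- list()
  with_seed(seed, {
    # blinks: Poisson count, uniform times, half-sine-squared waveform
    n_blinks <- stats::rpois(1, blink_rate_per_min * dur_min)
    if (n_blinks > 0 && blink_amplitude_uv > 0) {
      times <- sort(stats::runif(n_blinks, 0, rec_duration(rec) - blink_width_ms / 1000))
      wsamp <- round(blink_width_ms / 1000 * rec$fs)
      shape <- sin(pi * (seq_len(wsamp) - 1L) / (wsamp - 1L))^2
      for (t0 in times) {
        i0 <- onset_to_sample(t0, rec$fs) + 1L
        idx <- i0:min(n, i0 + wsamp - 1L)
        seg <- shape[seq_along(idx)]
        for (ch in seq_len(nch)) {
          data[ch, idx] <- data[ch, idx] +
            blink_amplitude_uv * blink_mixing[ch] * seg
        }
        log[[length(log) + 1L]] <- tibble::tibble(
          kind = "blink", onset_s = t0, peak_s = t0 + blink_width_ms / 2000,
          width_ms = blink_width_ms, amplitude_uv = blink_amplitude_uv)
      }
    }
    # muscle bursts: band-limited noise epochs, independent per channel
    n_bursts <- stats::rpois(1, muscle_rate_per_min * dur_min)
    if (n_bursts > 0 && muscle_rms_uv > 0) {
      times <- sort(stats::runif(n_bursts, 0, rec_duration(rec) - muscle_width_ms / 1000))
      wsamp <- round(muscle_width_ms / 1000 * rec$fs)
      taper <- sin(pi * (seq_len(wsamp) - 1L) / (wsamp - 1L))
      for (t0 in times) {
        i0 <- onset_to_sample(t0, rec$fs) + 1L
        idx <- i0:min(n, i0 + wsamp - 1L)
        for (ch in seq_len(nch)) {
          burst <- band_noise(wsamp, rec$fs, muscle_band)
          burst <- burst * muscle_rms_uv * taper
          data[ch, idx] <- data[ch, idx] + burst[seq_along(idx)]
        }
        log[[length(log) + 1L]] <- tibble::tibble(
          kind = "muscle", onset_s = t0, peak_s = t0 + muscle_width_ms / 2000,
          width_ms = muscle_width_ms, amplitude_uv = muscle_rms_uv)
      }
    }
  })
  log <- if (length(log)) dplyr::arrange(dplyr::bind_rows(log), .data$onset_s)
  else tibble::tibble(kind = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), width_ms = numeric(0),
                      amplitude_uv = numeric(0))
  list(recording = eeg_recording(data, rec$fs, rec$channel_labels, rec$schedule),
       log = log)
}
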