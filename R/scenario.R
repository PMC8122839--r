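#' Default oddball simulation scenario
#'
#' Parameter set emulating the validation study's oddball runs: three
#' exploring ear channels (reference subtraction assumed already applied) at
#' 1000 Hz, a 40-sequence / 10-tone oddball schedule with 2 s interstimulus
#' and 4 s intersequence gaps, a P300-like positivity (peak 24 uV at 400 ms)
#' on target events, a smaller early negativity on every tone, pink-noise
#' background with alpha and power-line components, and blink/muscle
#' artifacts at everyday rates.
#'
#' @param ... named overrides of any default element.
#' @return A named list of scenario parameters accepted by
#'   [simulate_oddball_recording()].
#' @export
#' @examples
#' sc <- default_scenario(n_sequences = 4)
#' sc$p300_amplitude_uv
default_scenario <- function(...) {
  defaults <- list(
    fs = 1000,
    n_channels = 3L,
    n_sequences = 40L,
    tones_per_sequence = 10L,
    target_position_choices = 7:10,
    isi_s = 2,
    inter_sequence_s = 4,
    tone_duration_s = 0.0698,
    lead_in_s = 2,
    tail_s = 2,
    one_over_f_exponent = 1,
    broadband_rms = 20,
    alpha_freq = 10, alpha_rms = 5,
    line_freq = 60, line_rms = 2,
    common_fraction = 0.3,
    p300_amplitude_uv = 24,
    p300_latency_ms = 400,
    p300_width_ms = 60,
    n1_amplitude_uv = -8,
    n1_latency_ms = 100,
    n1_width_ms = 30,
    erp_jitter_ms = 10,
    erp_channel_gains = c(0.7, 1, 1.3),
    blink_rate_per_min = 2,
    blink_amplitude_uv = 200,
    blink_width_ms = 250,
    blink_mixing = NULL,
    muscle_rate_per_min = 1,
    muscle_band = c(20, 45),
    muscle_rms_uv = 30,
    muscle_width_ms = 500
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, overrides)
}

#' Simulate a full oddball ear-EEG recording
#'
#' Composes the synthetic-data primitives into one participant-level
#' recording: oddball schedule, pink-noise background, ERP templates on the
#' scheduled events, and artifacts. The returned artifact log makes rejection
#' sensitivity/specificity computable exactly.
#'
#' @param scenario a scenario list from [default_scenario()].
#' @param seed integer seed; sub-seeds for schedule, background, ERP jitter
#'   and artifacts are derived deterministically from it.
#' @return A list with `recording` (an [eeg_recording()] carrying its
#'   schedule), `artifact_log` (tibble) and `scenario`.
#' @export
#' @examples
#' sim <- simulate_oddball_recording(default_scenario(n_sequences = 2), seed = 1)
#' sim$recording
simulate_oddball_recording <- function(scenario = default_scenario(),
                                       seed = 1L) {
  sc <- scenario
  seed <- as.numeric(seed)      # double arithmetic: derived sub-seeds cannot overflow
  sched <- generate_oddball_schedule(
    n_sequences = sc$n_sequences,
    tones_per_sequence = sc$tones_per_sequence,
    target_position_choices = sc$target_position_choices,
    isi_s = sc$isi_s, inter_sequence_s = sc$inter_sequence_s,
    tone_duration_s = sc$tone_duration_s,
    seed = seed * 7L + 1L)
  sched$onset_s <- sched$onset_s + sc$lead_in_s   # pre-roll so every epoch window fits
  duration <- max(sched$onset_s) + sc$tone_duration_s + sc$tail_s
  rec <- simulate_background(
    duration_s = duration, fs = sc$fs, n_channels = sc$n_channels,
    one_over_f_exponent = sc$one_over_f_exponent,
    broadband_rms = sc$broadband_rms,
    alpha_freq = sc$alpha_freq, alpha_rms = sc$alpha_rms,
    line_freq = sc$line_freq, line_rms = sc$line_rms,
    common_fraction = sc$common_fraction,
    seed = seed * 7L + 2L)
  templates <- dplyr::bind_rows(
    erp_template("target", sc$p300_latency_ms, sc$p300_width_ms,
                 sc$p300_amplitude_uv),
    erp_template("all", sc$n1_latency_ms, sc$n1_width_ms, sc$n1_amplitude_uv))
  gains <- sc$erp_channel_gains
  if (length(gains) != sc$n_channels) gains <- rep(1, sc$n_channels)
  rec <- add_erp_components(rec, sched, templates,
                            jitter_ms = sc$erp_jitter_ms,
                            channel_gains = gains,
                            seed = seed * 7L + 3L)
  art <- add_artifacts(
    rec,
    blink_rate_per_min = sc$blink_rate_per_min,
    blink_amplitude_uv = sc$blink_amplitude_uv,
    blink_width_ms = sc$blink_width_ms,
    blink_mixing = sc$blink_mixing,
    muscle_rate_per_min = sc$muscle_rate_per_min,
    muscle_band = sc$muscle_band,
    muscle_rms_uv = sc$muscle_rms_uv,
    muscle_width_ms = sc$muscle_width_ms,
    seed = seed * 7L + 4L)
  list(recording = art$recording, artifact_log = art$log, scenario = sc)
}

#' Simulate a steady-state (ASSR) ear-EEG recording
#'
#' Background activity plus a phase-locked component at the modulation
#' frequency, long enough for the sweep-averaging chain at the given sweep
#' configuration plus filter settle margins.
#'
#' @param fm modulation frequency, Hz. Default 41.
#' @param amplitude_uv ASSR amplitude at `fm`, uV.
#' @param harmonic_amplitudes amplitudes of harmonics of `fm`, uV.
#' @param duration_s recording duration, seconds.
#' @param fs sampling rate, Hz.
#' @param n_channels number of channels.
#' @param seed integer seed.
#' @param ... overrides forwarded to [simulate_background()]
#'   (`broadband_rms`, `alpha_rms`, `line_rms`, ...).
#' @return An [eeg_recording()].
#' @export
simulate_assr_recording <- function(fm = 41, amplitude_uv = 1,
                                    harmonic_amplitudes = numeric(0),
                                    duration_s = 100, fs = 1000,
                                    n_channels = 3L, seed = 1L, ...) {
  rec <- simulate_background(duration_s = duration_s, fs = fs,
                             n_channels = n_channels, seed = seed, ...)
  add_assr_component(rec, fm = fm, amplitude_uv = amplitude_uv,
                     harmonic_amplitudes = harmonic_amplitudes)
}
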