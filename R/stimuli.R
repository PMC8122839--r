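#' Generate an amplitude-modulated ASSR stimulus tone
#'
#' Synthesizes the sinusoidally amplitude-modulated tone used to evoke
#' auditory steady-state responses:
#' \deqn{y(t) = A \, \sin(2\pi f_c t) \cdot \frac{\sin(2\pi f_m t) + 1}{2}}
#' i.e. a carrier at `fc` whose envelope oscillates between 0 and `amplitude`
#' at the modulation rate `fm` (100% modulation depth). The one-sided spectrum
#' of this signal has exactly three components: the carrier at `fc` (half
#' amplitude) and two sidebands at `fc - fm` and `fc + fm` (quarter amplitude
#' each).
#'
#' @param fc carrier frequency in Hz (the audiometric test frequency).
#' @param fm modulation frequency in Hz; `fm = 0` yields an unmodulated
#'   carrier at half amplitude.
#' @param duration duration in seconds.
#' @param fs sampling rate in Hz; must exceed `2 * fc`. Default 16 kHz.
#' @param amplitude linear peak scale in `[0, 1]`.
#' @return A tibble with columns `time_s` and `amplitude` containing
#'   `round(duration * fs)` samples, with attributes `fs`, `fc`, `fm`.
#' @export
#' @examples
#' tone <- generate_am_tone(fc = 1000, fm = 41, duration = 1)
#' nrow(tone)
generate_am_tone <- function(fc, fm, duration, fs = 16000, amplitude = 1) {
  check_positive_scalar(fc, "fc")
  check_nonneg_scalar(fm, "fm")
  check_positive_scalar(duration, "duration")
  check_positive_scalar(fs, "fs")
  if (amplitude < 0 || amplitude > 1) {
    stop("`amplitude` must lie in [0, 1].", call. = FALSE)
  }
  if (fc <= fm) stop("`fc` must exceed `fm`.", call. = FALSE)
  if (fs <= 2 * fc) {
    stop(sprintf("sampling rate %g Hz violates fs > 2*fc with fc = %g Hz.", fs, fc),
         call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- amplitude * sin(2 * pi * fc * t) * (sin(2 * pi * fm * t) + 1) / 2
  out <- tibble::tibble(time_s = t, amplitude = y)
  attr(out, "fs") <- fs
  attr(out, "fc") <- fc
  attr(out, "fm") <- fm
  out
}

#' Generate a gated (rise/plateau/fall) sinusoidal tone
#'
#' Builds a short sinusoidal tone with raised-cosine (Hann) onset and offset
#' ramps and a flat plateau, the standard audiological gating used for
#' oddball stimuli. Total duration is `2 * rise_ms + plateau_ms`.
#'
#' @param tone_freq tone frequency in Hz.
#' @param rise_ms rise (and fall) time in milliseconds.
#' @param plateau_ms plateau duration in milliseconds.
#' @param fs sampling rate in Hz. Default 16 kHz.
#' @param amplitude linear peak scale.
#' @return A tibble with columns `time_s` and `amplitude`; attribute `fs`.
#' @export
#' @examples
#' tone <- generate_gated_tone(1000, rise_ms = 9.9, plateau_ms = 50)
#' max(tone$time_s) + 1 / attr(tone, "fs")  # 0.0698 s
generate_gated_tone <- function(tone_freq, rise_ms, plateau_ms, fs = 16000,
                                amplitude = 1) {
  check_positive_scalar(tone_freq, "tone_freq")
  check_nonneg_scalar(rise_ms, "rise_ms")
  check_nonneg_scalar(plateau_ms, "plateau_ms")
  check_positive_scalar(fs, "fs")
  duration_s <- (2 * rise_ms + plateau_ms) / 1000
  n <- round(duration_s * fs)
  if (n == 0L) {
    out <- tibble::tibble(time_s = numeric(0), amplitude = numeric(0))
    attr(out, "fs") <- fs
    return(out)
  }
  t <- (seq_len(n) - 1L) / fs
  n_rise <- round(rise_ms / 1000 * fs)
  env <- rep(1, n)
  if (n_rise > 0L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_rise) - 1L) / n_rise))  # Hann half-window
    env[seq_len(n_rise)] <- ramp
    env[n - seq_len(n_rise) + 1L] <- ramp
  }
  out <- tibble::tibble(time_s = t,
                        amplitude = amplitude * env * sin(2 * pi * tone_freq * t))
  attr(out, "fs") <- fs
  out
}

#' Generate an auditory oddball event schedule
#'
#' Builds the event schedule of an oddball run: `n_sequences` sequences of
#' `tones_per_sequence` tones each, every tone but one per sequence a
#' standard, the single target placed at a position drawn uniformly from
#' `target_position_choices`. Interstimulus and intersequence intervals are
#' offset-to-next-onset gaps.
#'
#' @param n_sequences number of sequences. Default 40.
#' @param tones_per_sequence tones per sequence. Default 10.
#' @param target_position_choices 1-based positions eligible to carry the
#'   target. Default `7:10`.
#' @param isi_s offset-to-onset interstimulus interval within a sequence, in
#'   seconds. Default 2.
#' @param inter_sequence_s offset-to-onset gap between sequences, in seconds.
#'   Default 4.
#' @param tone_duration_s duration of each tone in seconds. Default 0.0698
#'   (9.9 ms rise/fall + 50 ms plateau).
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @return A tibble with columns `onset_s`, `label` (`"standard"`/`"target"`),
#'   `sequence` (1-based), `position` (1-based within sequence).
#' @export
#' @examples
#' sched <- generate_oddball_schedule(seed = 1)
#' table(sched$label)
generate_oddball_schedule <- function(n_sequences = 40L,
                                      tones_per_sequence = 10L,
                                      target_position_choices = 7:10,
                                      isi_s = 2,
                                      inter_sequence_s = 4,
                                      tone_duration_s = 0.0698,
                                      seed = 1L) {
  check_positive_scalar(n_sequences, "n_sequences")
  check_positive_scalar(tones_per_sequence, "tones_per_sequence")
  check_nonneg_scalar(isi_s, "isi_s")
  check_nonneg_scalar(inter_sequence_s, "inter_sequence_s")
  check_positive_scalar(tone_duration_s, "tone_duration_s")
  if (length(target_position_choices) == 0L) {
    stop("`target_position_choices` must be nonempty.", call. = FALSE)
  }
  if (!all(target_position_choices %in% seq_len(tones_per_sequence))) {
    stop("`target_position_choices` must be positions within 1..tones_per_sequence.",
         call. = FALSE)
  }
  target_pos <- with_seed(seed, {
    target_position_choices[sample.int(length(target_position_choices),
                                       n_sequences, replace = TRUE)]
  })
  step <- tone_duration_s + isi_s
  seq_span <- (tones_per_sequence - 1L) * step + tone_duration_s
  seq_starts <- (seq_len(n_sequences) - 1L) * (seq_span + inter_sequence_s)
  pos <- seq_len(tones_per_sequence)
  tibble::tibble(
    sequence = rep(seq_len(n_sequences), each = tones_per_sequence),
    position = rep(pos, times = n_sequences),
    onset_s = rep(seq_starts, each = tones_per_sequence) + (pos - 1L) * step,
    label = ifelse(position == rep(target_pos, each = tones_per_sequence),
                   "target", "standard")
  )[, c("onset_s", "label", "sequence", "position")]
}

#' Total span of an oddball schedule
#'
#' Closed-form span from the first onset to the last tone offset.
#' @param schedule a schedule tibble from [generate_oddball_schedule()].
#' @param tone_duration_s tone duration in seconds.
#' @return Span in seconds.
#' @export
schedule_span <- function(schedule, tone_duration_s = 0.0698) {
  schedule <- validate_schedule(schedule)
  max(schedule$onset_s) + tone_duration_s - min(schedule$onset_s)
}

# Evaluate `expr` under `seed` and restore the session RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  expr
}
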