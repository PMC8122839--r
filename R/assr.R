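# ASSR detection chain: zero-phase FIR band-pass, contiguous sweep
# extraction, time-domain sweep averaging, FFT power spectrum, and
# neighbor-bin SNR at the modulation frequency.

#' Extract contiguous sweeps from a recording
#'
#' Segments the data stream into `n_sweeps` contiguous, non-overlapping
#' sweeps of `epochs_per_sweep * points_per_epoch` samples each (epochs are
#' contiguous; a steady-state response needs no stimulus-locked trigger when
#' the modulation completes an integer number of cycles per epoch). An
#' optional `settle` margin is discarded from each end first, to drop filter
#' edge transients.
#'
#' @param rec an [eeg_recording()].
#' @param n_sweeps number of sweeps. Default 6.
#' @param epochs_per_sweep epochs per sweep. Default 16.
#' @param points_per_epoch samples per epoch. Default 1000.
#' @param settle samples discarded at each end before segmentation. Default 0.
#' @return A `sweep_set`: list with `data` (sweeps x channels x samples
#'   array), `fs`, `channel_labels`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(96000), 1), fs = 1000)
#' sw <- extract_sweeps(rec)
#' dim(sw$data)  # 6 x 1 x 16000
extract_sweeps <- function(rec, n_sweeps = 6L, epochs_per_sweep = 16L,
                           points_per_epoch = 1000L, settle = 0L) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_positive_scalar(n_sweeps, "n_sweeps")
  check_positive_scalar(epochs_per_sweep, "epochs_per_sweep")
  check_positive_scalar(points_per_epoch, "points_per_epoch")
  check_nonneg_scalar(settle, "settle")
  sweep_len <- epochs_per_sweep * points_per_epoch
  required <- n_sweeps * sweep_len
  available <- n_samples(rec) - 2L * settle
  if (available < required) {
    stop(sprintf(
      "insufficient samples for sweep extraction: %d required (%d sweeps x %d samples), %d available after discarding %d settle samples per end.",
      required, n_sweeps, sweep_len, max(0L, available), settle), call. = FALSE)
  }
  nch <- n_channels(rec)
  out <- array(0, dim = c(n_sweeps, nch, sweep_len))
  for (s in seq_len(n_sweeps)) {
    idx <- settle + (s - 1L) * sweep_len + seq_len(sweep_len)
    out[s, , ] <- rec$data[, idx, drop = FALSE]
  }
  structure(list(data = out, fs = rec$fs, channel_labels = rec$channel_labels),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sweep_set> %d sweep(s) x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Average sweeps and compute the one-sided power spectrum
#'
#' Averages sweeps pointwise in the time domain per channel, then transforms
#' the mean sweep with a rectangular-window FFT. Power is one-sided in uV^2
#' (a unit-amplitude sinusoid on an exact bin carries 0.5 uV^2); frequency
#' resolution is `fs / sweep_length`.
#'
#' @param sweeps a `sweep_set` from [extract_sweeps()].
#' @return A tibble (`power_spectrum`) with columns `channel`, `freq_hz`,
#'   `power_uv2`; attributes `fs` and `resolution_hz`.
#' @export
average_and_spectrum <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  d <- dim(sweeps$data)
  if (d[1] < 1L) stop("sweep set is empty.", call. = FALSE)
  n <- d[3]
  n_keep <- floor(n / 2) + 1L
  freqs <- (seq_len(n_keep) - 1L) * sweeps$fs / n
  out <- purrr::map_dfr(seq_len(d[2]), function(ch) {
    mean_sweep <- colMeans(matrix(sweeps$data[, ch, ], nrow = d[1]))
    X <- stats::fft(mean_sweep) / n
    p <- Mod(X[seq_len(n_keep)])^2
    # fold negative-frequency power into the one-sided spectrum
    interior <- 2:(n_keep - if (n %% 2L == 0L) 1L else 0L)
    p[interior] <- 2 * p[interior]
    tibble::tibble(channel = sweeps$channel_labels[ch],
                   freq_hz = freqs, power_uv2 = p)
  })
  attr(out, "fs") <- sweeps$fs
  attr(out, "resolution_hz") <- sweeps$fs / n
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Neighbor-bin SNR at a target frequency
#'
#' Signal power is the spectrum bin nearest `f_target`; noise power is the
#' mean over `neighbor_halfwidth_bins` bins on each side, excluding
#' `guard_bins` immediately adjacent bins (and the target bin itself). SNR in
#' dB is `10 log10(signal / noise)`; a zero noise floor yields `Inf`.
#'
#' @param spectrum a `power_spectrum` tibble from [average_and_spectrum()].
#' @param f_target target frequency, Hz (e.g. the modulation frequency).
#' @param neighbor_halfwidth_bins half-width of the noise neighborhood in
#'   bins. Default 60.
#' @param guard_bins adjacent bins excluded from the noise estimate on each
#'   side. Default 2.
#' @return A tibble with one row per channel: `channel`, `f_target_hz`,
#'   `signal_power_uv2`, `noise_power_uv2`, `snr_db`, `neighbor_bins_used`.
#' @export
compute_snr <- function(spectrum, f_target, neighbor_halfwidth_bins = 60L,
                        guard_bins = 2L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  check_positive_scalar(f_target, "f_target")
  if (!(neighbor_halfwidth_bins > guard_bins && guard_bins >= 0)) {
    stop("need neighbor_halfwidth_bins > guard_bins >= 0.", call. = FALSE)
  }
  res <- attr(spectrum, "resolution_hz")
  purrr::map_dfr(split(spectrum, spectrum$channel), function(sp) {
    sp <- sp[order(sp$freq_hz), ]
    if (f_target < min(sp$freq_hz) || f_target > max(sp$freq_hz)) {
      stop("`f_target` lies outside the spectrum range.", call. = FALSE)
    }
    k <- which.min(abs(sp$freq_hz - f_target))
    lo <- k - neighbor_halfwidth_bins
    hi <- k + neighbor_halfwidth_bins
    if (lo < 1L || hi > nrow(sp)) {
      stop("neighbor window exceeds the spectrum bounds; reduce neighbor_halfwidth_bins.",
           call. = FALSE)
    }
    nb <- setdiff(lo:hi, (k - guard_bins):(k + guard_bins))
    signal_p <- sp$power_uv2[k]
    noise_p <- mean(sp$power_uv2[nb])
    tibble::tibble(
      channel = sp$channel[1],
      f_target_hz = sp$freq_hz[k],
      signal_power_uv2 = signal_p,
      noise_power_uv2 = noise_p,
      snr_db = if (noise_p > 0) 10 * log10(signal_p / noise_p) else Inf,
      neighbor_bins_used = length(nb))
  })
}

#' Run the full ASSR chain on a recording
#'
#' Band-pass filter (zero phase), discard filter settle margins, extract
#' sweeps, average in the time domain, FFT, and measure SNR at the
#' modulation frequency.
#'
#' @param rec an [eeg_recording()].
#' @param fm modulation frequency, Hz. Default 41.
#' @param low_hz,high_hz,order band-pass configuration (defaults 0.1 Hz to
#'   Nyquist-capped 500 Hz, order 500).
#' @param n_sweeps,epochs_per_sweep,points_per_epoch sweep configuration.
#' @param neighbor_halfwidth_bins,guard_bins SNR neighborhood configuration.
#' @return A list with `spectrum` (tibble) and `snr` (tibble).
#' @export
run_assr <- function(rec, fm = 41, low_hz = 0.1, high_hz = 500, order = 500L,
                     n_sweeps = 6L, epochs_per_sweep = 16L,
                     points_per_epoch = 1000L,
                     neighbor_halfwidth_bins = 60L, guard_bins = 2L) {
  high_hz <- min(high_hz, rec$fs / 2)
  filtered <- bandpass_fir(rec, low_hz, high_hz, order)
  settle <- max(order, round(rec$fs))
  sweeps <- extract_sweeps(filtered, n_sweeps, epochs_per_sweep,
                           points_per_epoch, settle = settle)
  spectrum <- average_and_spectrum(sweeps)
  snr <- compute_snr(spectrum, fm, neighbor_halfwidth_bins, guard_bins)
  list(spectrum = spectrum, snr = snr)
}
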