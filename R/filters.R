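# FIR design and zero-phase application.
#
# High-pass kernels are designed by spectral inversion (unit impulse minus a
# unit-DC-gain windowed-sinc low-pass): this pins the DC gain to exactly zero
# at any order, which a plain windowed-sinc high-pass cannot achieve when the
# cutoff sits far below the first transition-band width (0.1 Hz at fs 1000
# with a few hundred taps). Application is single-pass FFT convolution with
# the group delay of the symmetric kernel compensated exactly, i.e. a
# zero-net-phase linear-phase filter.

fir_lowpass <- function(order, cutoff_hz, fs) {
  if (order %% 2L != 0L) order <- order + 1L
  signal::fir1(order, 2 * cutoff_hz / fs, type = "low")
}

fir_highpass <- function(order, cutoff_hz, fs) {
  if (order %% 2L != 0L) order <- order + 1L
  h <- signal::fir1(order, 2 * cutoff_hz / fs, type = "low")
  h <- h / sum(h)                      # exact unit DC gain for the low-pass
  d <- numeric(order + 1L)
  d[order / 2L + 1L] <- 1
  d - h
}

# Zero-net-phase application of a symmetric odd-length kernel via FFT overlap
# of the whole signal; the (length(h)-1)/2 sample delay is removed exactly.
apply_fir_zerophase <- function(x, h) {
  n <- length(x)
  m <- length(h)
  stopifnot(m %% 2L == 1L)
  half <- (m - 1L) %/% 2L
  # reflect-pad so edges see a continuation rather than zeros
  pad <- min(half, n - 1L)
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  nfft <- stats::nextn(length(xp) + m - 1L, factors = c(2, 3, 5))
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  H <- stats::fft(c(h, numeric(nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(pad + half + 1L):(pad + half + n)]
}

apply_fir_matrix <- function(data, h) {
  t(apply(data, 1L, apply_fir_zerophase, h = h))
}

#' Zero-phase FIR band-pass filter for EEG recordings
#'
#' Applies a linear-phase FIR filter with exact group-delay compensation
#' (zero net phase), so peak latencies are preserved. When `high_hz` reaches
#' the Nyquist frequency the filter degenerates to a pure high-pass: a
#' low-pass at Nyquist is a no-op, and anti-aliasing is assumed to have been
#' handled at acquisition. When `low_hz > 0` the DC component is removed
#' exactly (the high-pass kernel has zero DC gain by construction).
#'
#' @param rec an [eeg_recording()].
#' @param low_hz lower band edge in Hz (`0` disables the high-pass).
#' @param high_hz upper band edge in Hz (`fs/2` disables the low-pass).
#' @param order FIR order (number of taps minus one); rounded up to even.
#' @return A filtered [eeg_recording()] of identical dimensions.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(sin(2 * pi * 41 * (0:9999) / 1000), 1), 1000)
#' filtered <- bandpass_fir(rec, 0.1, 500, order = 500)
bandpass_fir <- function(rec, low_hz, high_hz, order = 500L) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_nonneg_scalar(low_hz, "low_hz")
  check_positive_scalar(high_hz, "high_hz")
  nyq <- rec$fs / 2
  if (low_hz >= high_hz || high_hz > nyq) {
    stop(sprintf("band edges must satisfy 0 <= low < high <= fs/2 (= %g Hz).", nyq),
         call. = FALSE)
  }
  order <- as.integer(order)
  if (order < 2L) stop("`order` must be at least 2.", call. = FALSE)
  data <- rec$data
  if (low_hz > 0) {
    data <- apply_fir_matrix(data, fir_highpass(order, low_hz, rec$fs))
  }
  if (high_hz < nyq) {
    data <- apply_fir_matrix(data, fir_lowpass(order, high_hz, rec$fs))
  }
  eeg_recording(data, rec$fs, rec$channel_labels, rec$schedule)
}

#' Zero-phase moving-average smoother
#'
#' Boxcar FIR of `order + 1` taps applied with zero net phase; the output has
#' the same length as the input via symmetric edge padding. Used as the final
#' smoothing stage of the ERP chain.
#'
#' @param series numeric vector.
#' @param order FIR order; the kernel has `order + 1` taps. Rounded up to even
#'   so the kernel is symmetric about a center tap.
#' @return Smoothed numeric vector, same length as `series`.
#' @export
smooth_moving_average <- function(series, order = 8L) {
  order <- as.integer(order)
  if (order %% 2L != 0L) order <- order + 1L
  m <- order + 1L
  if (length(series) <= m) {
    stop(sprintf("series (length %d) must be longer than the %d-tap kernel.",
                 length(series), m), call. = FALSE)
  }
  apply_fir_zerophase(series, rep(1 / m, m))
}

# Resample to a lower rate: anti-alias FIR low-pass (0.8 x new Nyquist,
# order 100) then interpolation onto the uniform target grid. Output length is
# floor(n * fs_new / fs_old).
resample_recording <- function(rec, fs_new, aa_order = 100L) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_positive_scalar(fs_new, "fs_new")
  if (fs_new > rec$fs) {
    stop("resampling target rate exceeds the input rate.", call. = FALSE)
  }
  if (fs_new == rec$fs) return(rec)
  h <- fir_lowpass(aa_order, 0.8 * fs_new / 2, rec$fs)
  filtered <- apply_fir_matrix(rec$data, h)
  n_out <- floor(ncol(rec$data) * fs_new / rec$fs)
  t_old <- (seq_len(ncol(rec$data)) - 1L) / rec$fs
  t_new <- (seq_len(n_out) - 1L) / fs_new
  data <- t(apply(filtered, 1L, function(ch) {
    stats::approx(t_old, ch, xout = t_new, rule = 2)$y
  }))
  eeg_recording(data, fs_new, rec$channel_labels, rec$schedule)
}

# Analytic signal via the frequency-domain Hilbert construction; |analytic|
# is the amplitude envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2L + 1L] <- 1; w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1; w[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}
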