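test_that("band-pass filter removes DC and preserves passband tones", {
  const <- eeg_recording(matrix(10, 1, 10000), 1000)
  f <- bandpass_fir(const, 0.1, 500, order = 500)
  expect_lt(mean(abs(f$data[1, 1001:9000])), 0.01)

  t <- (0:9999) / 1000
  s41 <- eeg_recording(matrix(sin(2 * pi * 41 * t), 1), 1000)
  f41 <- bandpass_fir(s41, 0.1, 500, order = 500)
  gain <- stats::sd(f41$data[1, 2001:8000]) / stats::sd(s41$data[1, 2001:8000])
  expect_equal(gain, 1, tolerance = 0.01)

  expect_error(bandpass_fir(s41, 0.1, 600), "band edges")
  expect_error(bandpass_fir(s41, -1, 500), "low_hz")
  expect_s3_class(bandpass_fir(s41, 0.1, 500), "eeg_recording")
})

test_that("sweep extraction enforces the exact-length contract", {
  n_req <- 6L * 16L * 1000L
  rec <- eeg_recording(matrix(stats::rnorm(n_req), 1), 1000)
  sw <- extract_sweeps(rec)
  expect_equal(dim(sw$data), c(6, 1, 16000))

  short <- eeg_recording(matrix(stats::rnorm(n_req - 1), 1), 1000)
  expect_error(extract_sweeps(short), "96000 required")

  # settle margin shifts the segmentation
  padded <- eeg_recording(matrix(c(rep(0, 100), rec$data[1, ], rep(0, 100)), 1), 1000)
  sw2 <- extract_sweeps(padded, settle = 100)
  expect_equal(sw2$data, sw$data)
})

test_that("sweep averaging and FFT satisfy exact-bin arithmetic", {
  # identical sweeps: the mean is any single sweep
  x <- stats::rnorm(16000)
  rec <- eeg_recording(matrix(rep(x, 3), 1), 1000)
  sw <- extract_sweeps(rec, n_sweeps = 3)
  sp <- average_and_spectrum(sw)
  pg_direct <- periodogram(x, 1000)
  k <- which.min(abs(sp$freq_hz - 10))
  expect_equal(sp$power_uv2[k], 2 * pg_direct$power[k], tolerance = 1e-9)

  # 41 Hz unit sinusoid: 41 is an exact multiple of 1/16 Hz
  t <- (0:15999) / 1000
  rec41 <- eeg_recording(matrix(sin(2 * pi * 41 * t), 1), 1000)
  sp41 <- average_and_spectrum(extract_sweeps(rec41, n_sweeps = 1))
  k41 <- which(sp41$freq_hz == 41)
  expect_equal(sp41$power_uv2[k41], 0.5, tolerance = 1e-9)
  expect_lt(sum(sp41$power_uv2[-k41]), 1e-9)

  zeros <- average_and_spectrum(extract_sweeps(
    eeg_recording(matrix(0, 1, 16000), 1000), n_sweeps = 1))
  expect_true(all(zeros$power_uv2 == 0))
})

test_that("neighbor-bin SNR follows its defining arithmetic", {
  flat <- tibble::tibble(channel = "ch1", freq_hz = seq(0, 500, by = 1 / 16),
                         power_uv2 = 1)
  attr(flat, "fs") <- 1000; attr(flat, "resolution_hz") <- 1 / 16
  class(flat) <- c("power_spectrum", class(flat))
  expect_equal(compute_snr(flat, 41)$snr_db, 0)

  tenx <- flat
  tenx$power_uv2[tenx$freq_hz == 41] <- 10
  expect_equal(compute_snr(tenx, 41)$snr_db, 10 * log10(10), tolerance = 1e-9)

  lone <- flat
  lone$power_uv2 <- 0
  lone$power_uv2[lone$freq_hz == 41] <- 1
  expect_equal(compute_snr(lone, 41)$snr_db, Inf)

  expect_error(compute_snr(flat, 41, neighbor_halfwidth_bins = 2, guard_bins = 3),
               "neighbor_halfwidth_bins > guard_bins")
  expect_error(compute_snr(flat, 1e5), "outside the spectrum")
})

test_that("measured SNR increases with injected steady-state amplitude", {
  amps <- c(0.25, 0.5, 1, 2)
  mean_snr <- vapply(amps, function(a) {
    mean(vapply(1:10, function(sd) {
      rec <- simulate_assr_recording(fm = 41, amplitude_uv = a,
                                     duration_s = 98, fs = 1000,
                                     n_channels = 1, seed = 100 + sd)
      run_assr(rec)$snr$snr_db
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_snr) > 0))
})

test_that("a second-harmonic component is detectable at 82 Hz", {
  snr82 <- function(harm, sd) {
    rec <- simulate_assr_recording(fm = 41, amplitude_uv = 1,
                                   harmonic_amplitudes = harm,
                                   duration_s = 98, fs = 1000,
                                   n_channels = 1, seed = sd)
    out <- run_assr(rec)
    compute_snr(out$spectrum, 82)$snr_db
  }
  with_h <- mean(vapply(1:5, function(s) snr82(0.5, 200 + s), numeric(1)))
  without <- mean(vapply(1:5, function(s) snr82(numeric(0), 200 + s), numeric(1)))
  expect_gt(with_h - without, 3)
})

test_that("41 Hz SNR is invariant to the acquisition rate at matched resolution", {
  snr_at <- function(fs, sd) {
    rec <- simulate_assr_recording(fm = 41, amplitude_uv = 1,
                                   duration_s = 96 + 2 * max(500, fs) / fs + 0.5,
                                   fs = fs, n_channels = 1, seed = sd)
    run_assr(rec, points_per_epoch = fs)$snr$snr_db
  }
  seeds <- 300 + 1:20
  m1000 <- mean(vapply(seeds, function(s) snr_at(1000, s), numeric(1)))
  m4000 <- mean(vapply(seeds, function(s) snr_at(4000, s), numeric(1)))
  expect_lt(abs(m1000 - m4000), 1)
})
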