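test_that("background simulation has the requested shape and spectrum", {
  bg <- simulate_background(10, 1000, 3, seed = 1)
  expect_equal(dim(bg$data), c(3, 10000))

  # log-log periodogram slope over 1-100 Hz: average over 20 x 10 s segments
  long <- simulate_background(200, 500, 1, one_over_f_exponent = 1,
                              alpha_rms = 0, line_rms = 0,
                              common_fraction = 0, seed = 2)
  segs <- matrix(long$data[1, ], nrow = 5000)
  pows <- 0
  for (k in seq_len(ncol(segs))) pows <- pows + periodogram(segs[, k], 500)$power
  freqs <- periodogram(segs[, 1], 500)$freq_hz
  sel <- freqs >= 1 & freqs <= 100
  fit <- stats::lm(log10(pows[sel]) ~ log10(freqs[sel]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.15)
})

test_that("independent realizations are uncorrelated without a common source", {
  a <- simulate_background(30, 250, 1, common_fraction = 0, seed = 10)
  b <- simulate_background(30, 250, 1, common_fraction = 0, seed = 20)
  expect_lt(abs(stats::cor(a$data[1, ], b$data[1, ])), 0.2)
})

test_that("component additions are additive and commute", {
  sched <- generate_oddball_schedule(n_sequences = 2, seed = 3)
  dur <- schedule_span(sched) + 2
  bg <- simulate_background(dur, 250, 2, seed = 4)
  tpl <- erp_template("target", 400, 60, 24)
  ab <- add_erp_components(add_assr_component(bg, 41, 1), sched, tpl, seed = 5)
  ba <- add_assr_component(add_erp_components(bg, sched, tpl, seed = 5), 41, 1)
  expect_equal(ab$data, ba$data, tolerance = 1e-12)
})

test_that("steady-state component places power at fm and harmonics", {
  zero <- eeg_recording(matrix(0, 1, 16000), 1000)
  expect_identical(add_assr_component(zero, 41, 0)$data, zero$data)

  pure <- add_assr_component(zero, 41, 1)
  pg <- periodogram(pure$data[1, ], 1000)
  expect_equal(pg$freq_hz[which.max(pg$power)], 41)

  harm <- add_assr_component(zero, 41, 1, harmonic_amplitudes = 0.5)
  pg2 <- periodogram(harm$data[1, ], 1000)
  peak82 <- pg2$power[which.min(abs(pg2$freq_hz - 82))]
  expect_gt(peak82, 0.9 * 0.5^2 / 4)   # one-sided power of a 0.5 uV sinusoid

  expect_error(add_assr_component(zero, 41, 1, harmonic_amplitudes = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1)),
               "Nyquist")
})

test_that("ERP deflections are recovered exactly on a quiet background", {
  sched <- generate_oddball_schedule(n_sequences = 2, seed = 6)
  dur <- schedule_span(sched) + 2
  zero <- eeg_recording(matrix(0, 2, round(dur * 1000)), 1000)
  tpl <- erp_template("target", 350, 50, 10)
  rec <- add_erp_components(zero, sched, tpl, jitter_ms = 0)

  target_on <- sched$onset_s[sched$label == "target"][1]
  idx_peak <- which.max(rec$data[1, ])
  expect_equal(idx_peak - 1, round((target_on + 0.350) * 1000), tolerance = 1)

  # standard-event neighborhoods stay silent
  std_on <- sched$onset_s[sched$label == "standard"][3]
  idx <- round(std_on * 1000) + seq(200, 600)
  expect_equal(max(abs(rec$data[, idx])), 0, tolerance = 1e-8)

  # linearity: doubling the template doubles the peak
  rec2 <- add_erp_components(zero, sched, erp_template("target", 350, 50, 20),
                             jitter_ms = 0)
  expect_equal(max(rec2$data[1, ]), 2 * max(rec$data[1, ]), tolerance = 1e-9)
})

test_that("events whose template overruns the recording are skipped with a warning", {
  sched <- tibble::tibble(onset_s = c(1, 9.8), label = c("target", "target"),
                          sequence = c(1L, 2L))
  zero <- eeg_recording(matrix(0, 1, 10000), 1000)
  expect_warning(
    rec <- add_erp_components(zero, sched, erp_template("target", 400, 60, 24),
                              jitter_ms = 0),
    "skipped")
  expect_gt(max(rec$data), 20)     # first event still inserted
})

test_that("artifact insertion is logged and Poisson-calibrated", {
  bg <- simulate_background(30, 250, 2, seed = 7)
  none <- add_artifacts(bg, blink_rate_per_min = 0, muscle_rate_per_min = 0,
                        seed = 8)
  expect_identical(none$recording$data, bg$data)
  expect_equal(nrow(none$log), 0)

  long <- simulate_background(600, 250, 2, seed = 9)
  art <- add_artifacts(long, blink_rate_per_min = 4, muscle_rate_per_min = 0,
                       seed = 10)
  n_blinks <- sum(art$log$kind == "blink")
  expect_gte(n_blinks, stats::qpois(0.005, 40))
  expect_lte(n_blinks, stats::qpois(0.995, 40))
  expect_true(all(diff(art$log$onset_s) >= 0))
})
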