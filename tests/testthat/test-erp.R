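test_that("preprocessing yields 128 Hz output with the designed band", {
  rec <- eeg_recording(matrix(stats::rnorm(10000), 1), 1000)
  pp <- preprocess_erp(rec)
  expect_equal(ncol(pp$data), 1280)
  expect_equal(pp$fs, 128)

  const <- eeg_recording(matrix(7.3, 1, 20000), 1000)
  ppc <- preprocess_erp(const)
  expect_lt(mean(abs(ppc$data)), 0.01)

  t <- (0:19999) / 1000
  probe <- eeg_recording(matrix(sin(2 * pi * 45 * t), 1), 1000)
  ppp <- preprocess_erp(probe)
  out_rms <- stats::sd(ppp$data[1, 300:2000])
  expect_lt(20 * log10(out_rms / (1 / sqrt(2))), -20)

  expect_error(preprocess_erp(eeg_recording(matrix(0:99 * 1.0, 1), 50)),
               "low-pass cutoff")
})

test_that("epoching windows, labels and baseline correction are exact", {
  sched <- generate_oddball_schedule(seed = 11)
  sched$onset_s <- sched$onset_s + 1          # pre-roll for the 500 ms pre-window
  dur <- schedule_span(sched) + 3
  rec <- simulate_background(dur, 128, 2, seed = 12)
  rec$schedule <- sched
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[1], 400)
  expect_equal(dim(ep$data)[3], 192)
  expect_identical(ep$labels, sched$label)

  bl <- ep$time_ms >= -500 & ep$time_ms < 0
  for (e in c(1, 57, 400)) {
    expect_equal(mean(ep$data[e, 1, bl]), 0, tolerance = 1e-9)
    expect_equal(mean(ep$data[e, 2, bl]), 0, tolerance = 1e-9)
  }

  # an event too close to the start is dropped and counted
  early <- tibble::tibble(onset_s = c(0.1, 5), label = c("standard", "target"),
                          sequence = 1:2)
  ep2 <- epoch_and_baseline(eeg_recording(matrix(stats::rnorm(128 * 10), 1), 128),
                            early)
  expect_equal(ep2$n_dropped, 1L)
  expect_equal(dim(ep2$data)[1], 1)

  out <- tibble::tibble(onset_s = 100, label = "target", sequence = 1L)
  expect_error(epoch_and_baseline(eeg_recording(matrix(0.0 + 1:128, 1), 128), out),
               "outside the recording")
})

test_that("moving-average smoothing has unit DC gain and zero phase", {
  expect_equal(smooth_moving_average(rep(5, 100)), rep(5, 100),
               tolerance = 1e-9)

  set.seed(99)
  w <- stats::rnorm(10000)
  sm <- smooth_moving_average(w, order = 8)
  expect_equal(stats::var(sm), 1 / 9, tolerance = 0.1 / 9 * 10)

  tri <- c(seq(0, 1, length.out = 25), seq(1, 0, length.out = 25)[-1])
  pad <- c(rep(0, 30), tri, rep(0, 30))
  expect_equal(which.max(smooth_moving_average(pad)), which.max(pad))

  expect_error(smooth_moving_average(1:5, order = 8), "longer than")
})

test_that("grand averaging excludes under-channeled participants and is linear", {
  time_ms <- seq(-500, 992.1875, by = 1000 / 128)
  wave <- function(a) {
    dplyr::bind_rows(
      tibble::tibble(condition = "standard", time_ms = time_ms,
                     amplitude_uv = 0, n_epochs = 10),
      tibble::tibble(condition = "target", time_ms = time_ms,
                     amplitude_uv = a * exp(-(time_ms - 400)^2 / 5000),
                     n_epochs = 5))
  }
  nine <- c(rep(list(wave(10)), 8), list(wave(1000)))
  res <- grand_average_and_difference(nine, n_channels_active = c(rep(3, 8), 1))
  expect_equal(res$n_participants, 8)
  expect_equal(res$n_excluded, 1)
  expect_equal(max(res$difference$amplitude_uv), 10, tolerance = 1e-3)

  # identical conditions give a null difference wave
  flat <- list(dplyr::mutate(wave(0), amplitude_uv = 3))
  res0 <- grand_average_and_difference(flat, n_channels_active = 2)
  expect_true(all(res0$difference$amplitude_uv == 0))

  # w and -w cancel in the grand average
  res_pm <- grand_average_and_difference(
    list(wave(10), dplyr::mutate(wave(10), amplitude_uv = -.data$amplitude_uv)),
    n_channels_active = c(3, 3))
  expect_equal(max(abs(res_pm$difference$amplitude_uv)), 0, tolerance = 1e-12)

  expect_error(grand_average_and_difference(nine,
                                            n_channels_active = rep(1, 9)),
               "no admissible")
})

test_that("P300 measurement recovers noise-free peaks and honors the tie rule", {
  time_ms <- seq(-500, 992.1875, by = 1000 / 128)
  gauss <- tibble::tibble(time_ms = time_ms,
                          amplitude_uv = 10 * exp(-(time_ms - 350)^2 / (2 * 60^2)))
  p <- measure_p300(gauss)
  expect_equal(p$amplitude_uv, 10, tolerance = 0.01)
  expect_lte(abs(p$latency_ms - 350), 1000 / 128)

  flat <- tibble::tibble(time_ms = time_ms, amplitude_uv = 0)
  pf <- measure_p300(flat)
  expect_equal(pf$amplitude_uv, 0)
  expect_equal(pf$latency_ms, min(time_ms[time_ms >= 250]))

  expect_error(measure_p300(gauss, search_window_ms = c(250, 2000)),
               "beyond the epoch")
})

test_that("the chain is scale-equivariant up to rejection", {
  sc <- default_scenario(n_sequences = 6)
  sim <- simulate_oddball_recording(sc, seed = 31)
  run_diff <- function(rec) {
    out <- run_erp_participant(rec, seed = 31)
    res <- grand_average_and_difference(list(out$erp), 3)
    res$difference$amplitude_uv
  }
  d1 <- run_diff(sim$recording)
  scaled <- eeg_recording(3 * sim$recording$data, sim$recording$fs,
                          sim$recording$channel_labels, sim$recording$schedule)
  d3 <- run_diff(scaled)
  expect_equal(d3, 3 * d1, tolerance = 1e-6)
})

test_that("the full chain recovers the injected P300 over repeated simulations", {
  sc <- default_scenario()
  rec <- purrr::map_dfr(1:20, function(sd) {
    sim <- simulate_oddball_recording(sc, seed = 500 + sd)
    out <- run_erp_participant(sim$recording, seed = 500 + sd)
    measure_p300(grand_average_and_difference(list(out$erp), sc$n_channels))
  })
  expect_equal(mean(rec$amplitude_uv), sc$p300_amplitude_uv, tolerance = 0.2)
  expect_lt(abs(mean(rec$latency_ms) - sc$p300_latency_ms), 40)
})

test_that("rejection lowers the recovery error on contaminated recordings", {
  # ICA is disabled in both arms so the comparison isolates the epoch
  # screen: with blinks already projected out by ICA, rejection has no
  # artifacts left to catch
  sc <- default_scenario()
  rmse <- function(seed, reject) {
    sim <- simulate_oddball_recording(sc, seed = seed)
    out <- run_erp_participant(sim$recording, reject = reject,
                               run_ica = FALSE, seed = seed)
    res <- grand_average_and_difference(list(out$erp), sc$n_channels)
    tpl <- injected_difference_template(res$difference$time_ms, sc)
    sqrt(mean((res$difference$amplitude_uv - tpl)^2))
  }
  seeds <- 700 + 1:4
  with_rej <- vapply(seeds, rmse, numeric(1), reject = TRUE)
  without <- vapply(seeds, rmse, numeric(1), reject = FALSE)
  expect_lt(mean(with_rej - without), 0)
})
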