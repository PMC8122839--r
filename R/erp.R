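# Grand averaging, difference waves and P300 measurement, plus the
# participant- and study-level drivers that chain the full oddball ERP
# pipeline: preprocess -> ICA blink removal -> epoch + baseline ->
# probability/kurtosis rejection -> moving-average smoothing -> averages.

#' Per-condition average waveform of one participant
#'
#' Averages kept epochs by condition, then averages across channels, giving
#' one waveform per condition for the participant.
#'
#' @param epochs an `eeg_epochs` object (after rejection).
#' @param smooth_order moving-average FIR order applied to each epoch-average
#'   waveform; `0` disables smoothing. Default 8.
#' @return A tibble with columns `condition`, `time_ms`, `amplitude_uv`,
#'   `n_epochs`.
#' @export
participant_erp <- function(epochs, smooth_order = 8L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  purrr::map_dfr(c("standard", "target"), function(cond) {
    sel <- which(epochs$labels == cond & epochs$keep)
    if (length(sel) == 0L) return(NULL)
    nch <- dim(epochs$data)[2]
    avg <- apply(epochs$data[sel, , , drop = FALSE], 3L, mean)
    if (smooth_order > 0L) avg <- smooth_moving_average(avg, smooth_order)
    tibble::tibble(condition = cond, time_ms = epochs$time_ms,
                   amplitude_uv = avg, n_epochs = length(sel))
  })
}

#' Grand average and difference wave across participants
#'
#' Participants recorded with fewer than `min_channels` active channels are
#' excluded. Per admissible participant, kept epochs are averaged by
#' condition and across channels; the grand average is the unweighted mean
#' of participant waveforms; the difference wave is target minus standard,
#' pointwise.
#'
#' @param participant_erps list of per-participant tibbles from
#'   [participant_erp()].
#' @param n_channels_active integer vector: active channel count per
#'   participant (defaults to all admissible).
#' @param min_channels minimum active channels for inclusion. Default 2.
#' @return An `erp_result`: list with `grand_average` (tibble `condition`,
#'   `time_ms`, `amplitude_uv`), `difference` (tibble `time_ms`,
#'   `amplitude_uv`), `n_participants`, `n_excluded`.
#' @export
grand_average_and_difference <- function(participant_erps,
                                         n_channels_active = NULL,
                                         min_channels = 2L) {
  if (is.null(n_channels_active)) {
    n_channels_active <- rep(min_channels, length(participant_erps))
  }
  stopifnot(length(n_channels_active) == length(participant_erps))
  admissible <- n_channels_active >= min_channels
  if (!any(admissible)) {
    stop("no admissible participants: all have fewer than the minimum channel count.",
         call. = FALSE)
  }
  used <- participant_erps[admissible]
  stacked <- dplyr::bind_rows(used, .id = "participant")
  ga <- stacked |>
    dplyr::group_by(.data$condition, .data$time_ms) |>
    dplyr::summarise(amplitude_uv = mean(.data$amplitude_uv), .groups = "drop")
  wide <- tidyr::pivot_wider(ga, names_from = "condition",
                             values_from = "amplitude_uv")
  if (!all(c("standard", "target") %in% names(wide))) {
    stop("both conditions must be present to form a difference wave.",
         call. = FALSE)
  }
  diff <- tibble::tibble(time_ms = wide$time_ms,
                         amplitude_uv = wide$target - wide$standard)
  structure(list(grand_average = ga, difference = diff,
                 n_participants = sum(admissible),
                 n_excluded = sum(!admissible)),
            class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  p <- measure_p300(x)
  cat(sprintf("<erp_result> N = %d participant(s) (%d excluded)\n",
              x$n_participants, x$n_excluded))
  cat(sprintf("  difference-wave peak: %.1f uV at %.0f ms (250-600 ms window)\n",
              p$amplitude_uv, p$latency_ms))
  invisible(x)
}

#' Measure the P300 on a difference wave
#'
#' Amplitude is the maximum of the target-minus-standard difference wave
#' within the search window; latency is the time of that maximum, ties
#' broken to the earliest sample.
#'
#' @param result an `erp_result`, or a tibble with `time_ms` and
#'   `amplitude_uv`.
#' @param search_window_ms window searched, milliseconds. Default
#'   `c(250, 600)`.
#' @return A one-row tibble: `amplitude_uv`, `latency_ms`.
#' @export
measure_p300 <- function(result, search_window_ms = c(250, 600)) {
  wave <- if (inherits(result, "erp_result")) result$difference
  else tibble::as_tibble(result)
  stopifnot(all(c("time_ms", "amplitude_uv") %in% names(wave)))
  if (search_window_ms[1] < min(wave$time_ms) ||
      search_window_ms[2] > max(wave$time_ms)) {
    stop("search window extends beyond the epoch span.", call. = FALSE)
  }
  w <- wave[wave$time_ms >= search_window_ms[1] &
              wave$time_ms <= search_window_ms[2], ]
  w <- w[order(w$time_ms), ]
  k <- which.max(w$amplitude_uv)          # which.max takes the earliest tie
  tibble::tibble(amplitude_uv = w$amplitude_uv[k], latency_ms = w$time_ms[k])
}

#' Run the full ERP chain for one simulated or recorded participant
#'
#' preprocess -> ICA blink removal (only if all channels were active, as the
#' acquisition protocol requires) -> epoch + baseline -> statistical
#' rejection -> per-condition averages with moving-average smoothing.
#'
#' @param rec an [eeg_recording()] with an attached event schedule.
#' @param reject apply probability/kurtosis rejection. Default TRUE.
#' @param run_ica apply ICA blink removal. Default TRUE.
#' @param smooth_order moving-average order for the final smoothing.
#' @param sd_threshold rejection threshold (SD units).
#' @param hp_order,lp_order,resample_fs forwarded to [preprocess_erp()].
#' @param seed seed for the ICA initial rotation.
#' @return A list with `erp` (tibble from [participant_erp()]),
#'   `rejection_report` (tibble or NULL), `ica_removed` (component index or
#'   NA), `n_epochs`.
#' @export
run_erp_participant <- function(rec, reject = TRUE, run_ica = TRUE,
                                smooth_order = 8L, sd_threshold = 3,
                                hp_order = 500L, lp_order = 100L,
                                resample_fs = 128, seed = 1L) {
  pp <- preprocess_erp(rec, hp_order = hp_order, lp_order = lp_order,
                       resample_fs = resample_fs)
  ica_removed <- NA_integer_
  if (run_ica && n_channels(pp) >= 2L) {
    cleaned <- ica_blink_removal(pp, seed = seed)
    pp <- cleaned$recording
    ica_removed <- cleaned$removed
  }
  ep <- epoch_and_baseline(pp)
  report <- NULL
  if (reject) {
    rej <- reject_epochs(ep, sd_threshold = sd_threshold)
    ep <- rej$epochs
    report <- rej$report
  }
  list(erp = participant_erp(ep, smooth_order = smooth_order),
       rejection_report = report, ica_removed = ica_removed,
       n_epochs = dim(ep$data)[1])
}

#' Simulate and analyze a multi-participant oddball study
#'
#' Simulates `n_participants` independent recordings under `scenario`, runs
#' the full ERP chain on each, and returns the grand average, difference
#' wave and P300 measurement.
#'
#' @param n_participants number of simulated participants. Default 8.
#' @param scenario scenario list from [default_scenario()].
#' @param seed integer seed; participant sub-seeds derive from it.
#' @param ... forwarded to [run_erp_participant()].
#' @return A list with `result` (an `erp_result`), `p300` (tibble), and
#'   `participants` (list of per-participant outputs).
#' @export
run_erp_study <- function(n_participants = 8L, scenario = default_scenario(),
                          seed = 1L, ...) {
  parts <- purrr::map(seq_len(n_participants), function(p) {
    sub_seed <- (seed * 131L + p) %% .Machine$integer.max
    sim <- simulate_oddball_recording(scenario, seed = sub_seed)
    run_erp_participant(sim$recording, seed = sub_seed, ...)
  })
  res <- grand_average_and_difference(
    purrr::map(parts, "erp"),
    n_channels_active = rep(scenario$n_channels, n_participants))
  list(result = res, p300 = measure_p300(res), participants = parts)
}
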