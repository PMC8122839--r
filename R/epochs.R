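#' ERP preprocessing: high-pass, resample, low-pass
#'
#' The continuous-data front end of the oddball ERP chain: zero-phase FIR
#' high-pass at `hp_cutoff` (order `hp_order`), resampling to `resample_fs`,
#' then zero-phase FIR low-pass at `lp_cutoff` (order `lp_order`). Zero net
#' phase at every stage preserves component latencies.
#'
#' `hp_order` is specified at the analysis rate (`resample_fs`) and the
#' kernel length is scaled to the input rate before application, so the
#' high-pass realizes its nominal cutoff regardless of the acquisition rate:
#' an order-500 kernel spans 3.9 s at 128 Hz, long enough for a 0.1 Hz
#' transition, whereas the same tap count at 1000 Hz spans only 0.5 s and
#' would smear the transition band across 0-4 Hz, eating into slow ERP
#' components.
#'
#' @param rec an [eeg_recording()].
#' @param hp_cutoff high-pass cutoff, Hz. Default 0.1.
#' @param hp_order high-pass FIR order at the analysis rate. Default 500.
#' @param resample_fs target sampling rate, Hz. Default 128.
#' @param lp_cutoff low-pass cutoff, Hz. Default 30.
#' @param lp_order low-pass FIR order. Default 100.
#' @return A filtered [eeg_recording()] at `resample_fs`.
#' @export
preprocess_erp <- function(rec, hp_cutoff = 0.1, hp_order = 500L,
                           resample_fs = 128, lp_cutoff = 30, lp_order = 100L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * lp_cutoff) {
    stop("input sampling rate must exceed twice the low-pass cutoff.",
         call. = FALSE)
  }
  if (resample_fs > rec$fs) {
    stop("resampling target rate exceeds the input rate.", call. = FALSE)
  }
  hp_order_in <- round(hp_order * rec$fs / resample_fs)
  hp <- eeg_recording(apply_fir_matrix(rec$data, fir_highpass(hp_order_in, hp_cutoff, rec$fs)),
                      rec$fs, rec$channel_labels, rec$schedule)
  rs <- resample_recording(hp, resample_fs)
  lp <- apply_fir_matrix(rs$data, fir_lowpass(lp_order, lp_cutoff, rs$fs))
  eeg_recording(lp, rs$fs, rec$channel_labels, rec$schedule)
}

#' Epoch a recording around scheduled events and baseline-correct
#'
#' Cuts fixed windows (default -500 to 1000 ms) around every event onset and
#' subtracts, per epoch and channel, the mean over the baseline window
#' (default -500 to 0 ms, closed-open: the onset sample belongs to the
#' post-stimulus segment). Events whose window falls outside the recording
#' are dropped and counted.
#'
#' @param rec an [eeg_recording()] (typically the output of
#'   [preprocess_erp()]).
#' @param schedule event schedule tibble; defaults to the one attached to
#'   `rec`.
#' @param window_ms epoch window relative to onset, milliseconds.
#' @param baseline_ms baseline window, milliseconds (closed-open).
#' @return An `eeg_epochs` object: list with `data` (epochs x channels x
#'   samples array), `labels`, `time_ms`, `keep`, `fs`, `channel_labels`,
#'   `onsets_s`, `n_dropped`.
#' @export
epoch_and_baseline <- function(rec, schedule = rec$schedule,
                               window_ms = c(-500, 1000),
                               baseline_ms = c(-500, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(schedule) || nrow(schedule) == 0L) {
    stop("no events to epoch: schedule is empty.", call. = FALSE)
  }
  schedule <- validate_schedule(schedule)
  fs <- rec$fs
  pre <- round(-window_ms[1] / 1000 * fs)
  post <- round(window_ms[2] / 1000 * fs)
  len <- pre + post               # onset sample opens the post segment
  time_ms <- (seq_len(len) - pre - 1L) / fs * 1000
  onset_idx <- onset_to_sample(schedule$onset_s, fs) + 1L
  ok <- (onset_idx - pre) >= 1L & (onset_idx + post - 1L) <= n_samples(rec)
  n_dropped <- sum(!ok)
  if (!any(ok)) {
    stop("all events fall outside the recording span.", call. = FALSE)
  }
  kept <- which(ok)
  nch <- n_channels(rec)
  data <- array(0, dim = c(length(kept), nch, len))
  for (e in seq_along(kept)) {
    idx <- (onset_idx[kept[e]] - pre):(onset_idx[kept[e]] + post - 1L)
    data[e, , ] <- rec$data[, idx, drop = FALSE]
  }
  bl <- time_ms >= baseline_ms[1] & time_ms < baseline_ms[2]
  if (any(bl)) {
    for (e in seq_len(dim(data)[1])) {
      mu <- rowMeans(matrix(data[e, , bl], nrow = nch))
      data[e, , ] <- data[e, , ] - mu
    }
  }
  structure(
    list(data = data, labels = schedule$label[kept], time_ms = time_ms,
         keep = rep(TRUE, length(kept)), fs = fs,
         channel_labels = rec$channel_labels,
         onsets_s = schedule$onset_s[kept], n_dropped = n_dropped),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epoch(s) x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window %g..%g ms; kept %d/%d; labels: %s\n",
              min(x$time_ms), max(x$time_ms), sum(x$keep), d[1],
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Convert epochs to a long tibble
#' @param x an `eeg_epochs` object.
#' @param ... unused.
#' @return Tibble with `epoch`, `label`, `kept`, `channel`, `time_ms`,
#'   `amplitude_uv`.
#' @method as_tibble eeg_epochs
#' @export
as_tibble.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tidyr::expand_grid(epoch = seq_len(d[1]), channel = x$channel_labels,
                     time_ms = x$time_ms) |>
    dplyr::mutate(label = x$labels[.data$epoch],
                  kept = x$keep[.data$epoch],
                  amplitude_uv = as.vector(aperm(x$data, c(3, 2, 1)))) |>
    dplyr::select("epoch", "label", "kept", "channel", "time_ms",
                  "amplitude_uv")
}
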