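#' Multichannel EEG recording container
#'
#' An `eeg_recording` wraps a channels-by-samples numeric matrix in microvolts
#' together with its sampling rate, channel labels and (optionally) the event
#' schedule of the stimulation run that produced it. Analysis functions accept
#' and return this container; all derived quantities (spectra, SNR tables,
#' ERP waveforms, rejection reports) are tibbles.
#'
#' @param data numeric matrix, channels x samples, in microvolts. A vector is
#'   promoted to a single-channel matrix.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param schedule optional event schedule tibble with columns
#'   `onset_s`, `label`, `sequence` (see [generate_oddball_schedule()]).
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' rec
eeg_recording <- function(data, fs, channel_labels = NULL, schedule = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate in Hz.", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples.", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length must equal the number of channels.", call. = FALSE)
  }
  if (!is.null(schedule)) schedule <- validate_schedule(schedule)
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         schedule = schedule),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$schedule)) {
    cat(sprintf("  schedule: %d events (%d target)\n",
                nrow(x$schedule), sum(x$schedule$label == "target")))
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Convert a recording to a long tibble
#'
#' @param x an [eeg_recording()].
#' @param ... unused.
#' @return A tibble with columns `time_s`, `channel`, `amplitude_uv`.
#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  t <- (seq_len(ncol(x$data)) - 1L) / x$fs
  tibble::tibble(
    time_s = rep(t, times = nrow(x$data)),
    channel = rep(x$channel_labels, each = ncol(x$data)),
    amplitude_uv = as.vector(t(x$data))
  )
}

validate_schedule <- function(schedule) {
  schedule <- tibble::as_tibble(schedule)
  need <- c("onset_s", "label", "sequence")
  missing <- setdiff(need, names(schedule))
  if (length(missing)) {
    stop("schedule is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(schedule$onset_s, strictly = TRUE)) {
    stop("schedule onsets must be strictly increasing.", call. = FALSE)
  }
  if (!all(schedule$label %in% c("standard", "target"))) {
    stop("schedule labels must be 'standard' or 'target'.", call. = FALSE)
  }
  schedule
}

# shared argument checks ------------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar.", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a nonnegative finite scalar.", name), call. = FALSE)
  }
  invisible(x)
}

# onset (seconds) -> 0-based sample index, rounding half up
onset_to_sample <- function(onset_s, fs) {
  floor(onset_s * fs + 0.5)
}
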