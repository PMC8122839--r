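# Shared fixture builders: everything is generated in code at test time.

# Bare epochs container for rejection tests (epochs x channels x samples).
make_epochs <- function(data, labels = NULL, fs = 128) {
  d <- dim(data)
  structure(
    list(data = data,
         labels = labels %||% rep("standard", d[1]),
         time_ms = (seq_len(d[3]) - d[3] / 3 - 1) / fs * 1000,
         keep = rep(TRUE, d[1]),
         fs = fs,
         channel_labels = paste0("ch", seq_len(d[2])),
         onsets_s = seq_len(d[1]),
         n_dropped = 0L),
    class = "eeg_epochs")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# TRUE per epoch if any logged blink overlaps the epoch window.
blink_epoch_mask <- function(epochs, artifact_log,
                             window_s = c(-0.5, 1.0)) {
  blog <- artifact_log[artifact_log$kind == "blink", ]
  vapply(epochs$onsets_s, function(on) {
    lo <- on + window_s[1]; hi <- on + window_s[2]
    any(blog$onset_s < hi & (blog$onset_s + blog$width_ms / 1000) > lo)
  }, logical(1))
}

# Injected difference-wave template (channel-mean gain 1) on an epoch time
# axis, for recovery-error measurements.
injected_difference_template <- function(time_ms, scenario) {
  scenario$p300_amplitude_uv *
    exp(-(time_ms - scenario$p300_latency_ms)^2 /
          (2 * scenario$p300_width_ms^2))
}

# One-sided periodogram of a vector as a tibble.
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  n_keep <- floor(n / 2) + 1L
  tibble::tibble(freq_hz = (seq_len(n_keep) - 1L) * fs / n,
                 power = p[seq_len(n_keep)])
}
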