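# Statistical epoch rejection: joint-probability and kurtosis criteria.
#
# The probability criterion scores each epoch's joint log-likelihood under
# the empirical per-channel amplitude distribution (a histogram density over
# all epochs pooled), z-scored across epochs; improbable epochs (blinks,
# large transients) sit in the tails. The kurtosis criterion z-scores each
# epoch's excess kurtosis per channel; spiky epochs stand out. Both are
# applied per channel and pooled across channels; an epoch is rejected when
# any |z| exceeds the SD threshold.

#' Reject improbable and high-kurtosis epochs
#'
#' @param epochs an `eeg_epochs` object from [epoch_and_baseline()].
#' @param sd_threshold rejection threshold on the criterion z-scores, in
#'   standard deviations. Default 3.
#' @param n_bins histogram bins for the empirical amplitude density.
#'   Default 100.
#' @return A list with `epochs` (the input with `keep` updated) and `report`
#'   (tibble: `epoch`, `label`, per-criterion z-scores `prob_z_max`,
#'   `kurt_z_max`, `prob_z_pooled`, `kurt_z_pooled`, and `rejected`); the
#'   report carries attribute `rejected_fraction_pct`.
#' @export
#' @examples
#' rec <- simulate_oddball_recording(default_scenario(n_sequences = 3), seed = 2)
#' pp <- preprocess_erp(rec$recording)
#' ep <- epoch_and_baseline(pp)
#' rej <- reject_epochs(ep)
#' attr(rej$report, "rejected_fraction_pct")
reject_epochs <- function(epochs, sd_threshold = 3, n_bins = 100L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  n_ep <- d[1]; nch <- d[2]; len <- d[3]
  if (n_ep < 8L) {
    stop(sprintf("need at least 8 epochs for rejection z-scores; got %d.", n_ep),
         call. = FALSE)
  }
  check_positive_scalar(sd_threshold, "sd_threshold")

  # per-channel log-density from the pooled histogram
  logp <- array(0, dim = c(n_ep, nch))     # mean log-likelihood per epoch/channel
  kurt <- array(0, dim = c(n_ep, nch))
  for (ch in seq_len(nch)) {
    pooled <- as.vector(epochs$data[, ch, ])
    brks <- seq(min(pooled), max(pooled), length.out = n_bins + 1L)
    h <- graphics::hist(pooled, breaks = brks, plot = FALSE)
    dens <- pmax(h$density, 1e-12)
    for (e in seq_len(n_ep)) {
      x <- epochs$data[e, ch, ]
      bin <- pmin(pmax(findInterval(x, brks, all.inside = TRUE), 1L), n_bins)
      logp[e, ch] <- mean(log(dens[bin]))
      kurt[e, ch] <- excess_kurtosis(x)
    }
  }
  # channel-pooled measures
  logp_pooled <- rowMeans(logp)
  kurt_pooled <- vapply(seq_len(n_ep), function(e) {
    excess_kurtosis(as.vector(epochs$data[e, , ]))
  }, numeric(1))

  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  prob_z <- apply(logp, 2L, zs)
  kurt_z <- apply(kurt, 2L, zs)
  prob_z_pooled <- zs(logp_pooled)
  kurt_z_pooled <- zs(kurt_pooled)

  prob_z_max <- apply(abs(matrix(prob_z, nrow = n_ep)), 1L, max)
  kurt_z_max <- apply(abs(matrix(kurt_z, nrow = n_ep)), 1L, max)
  rejected <- prob_z_max > sd_threshold | kurt_z_max > sd_threshold |
    abs(prob_z_pooled) > sd_threshold | abs(kurt_z_pooled) > sd_threshold

  report <- tibble::tibble(
    epoch = seq_len(n_ep), label = epochs$labels,
    prob_z_max = prob_z_max, kurt_z_max = kurt_z_max,
    prob_z_pooled = prob_z_pooled, kurt_z_pooled = kurt_z_pooled,
    rejected = rejected)
  attr(report, "rejected_fraction_pct") <- 100 * sum(rejected) / n_ep
  epochs$keep <- epochs$keep & !rejected
  list(epochs = epochs, report = report)
}

excess_kurtosis <- function(x) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0) return(0)
  mean((x - mu)^4) / s2^2 - 3
}
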