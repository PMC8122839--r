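# Fixed-point ICA (negentropy maximization, tanh contrast, symmetric
# decorrelation) with PCA whitening and a seeded initial rotation, and an
# automated blink-component picker: among the unmixed sources, the one with
# the largest fraction of 0.5-4 Hz power that is also leptokurtic is the
# blink component.

fastica_decompose <- function(X, n_components = nrow(X), max_iter = 200L,
                              tol = 1e-6, seed = 1L) {
  nch <- nrow(X)
  if (nch < 2L) stop("ICA requires at least 2 channels.", call. = FALSE)
  n_components <- min(n_components, nch)
  center <- rowMeans(X)
  Xc <- X - center
  C <- (Xc %*% t(Xc)) / ncol(Xc)
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) < 1e-10 * max(eig$values)) {
    stop(paste("data are rank-deficient; ICA cannot separate as many",
               "components as channels. Drop duplicated/flat channels first."),
         call. = FALSE)
  }
  keep <- seq_len(n_components)
  K <- diag(1 / sqrt(eig$values[keep]), n_components) %*% t(eig$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc                                   # whitened: cov = I
  W <- with_seed(seed, {
    w0 <- matrix(stats::rnorm(n_components^2), n_components)
    sym_decorrelate(w0)
  })
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / ncol(Z) - diag(rowMeans(Gp), n_components) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  unmixing <- W %*% K                             # sources = unmixing %*% Xc
  mixing <- MASS_ginv(unmixing)
  list(sources = unmixing %*% Xc, unmixing = unmixing, mixing = mixing,
       center = center, n_iter = it, converged = delta < tol)
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# Moore-Penrose pseudoinverse via SVD (square/full-rank here, but safe).
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Fraction of source power in `band` (Hz) via the periodogram.
band_power_fraction <- function(x, fs, band = c(0.5, 4)) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  n_keep <- floor(n / 2) + 1L
  freqs <- (seq_len(n_keep) - 1L) * fs / n
  p <- p[seq_len(n_keep)]
  tot <- sum(p[freqs > 0])
  if (tot == 0) return(0)
  sum(p[freqs >= band[1] & freqs <= band[2]]) / tot
}

#' Remove the eye-blink component by ICA
#'
#' Unmixes the channels into as many independent components, identifies the
#' blink component automatically — the component whose time course has the
#' largest ratio of 0.5-4 Hz power to total power AND excess kurtosis above
#' `kurtosis_floor` (blinks are sparse, slow, large) — zeroes it, and remixes
#' back to the channel space. If no component qualifies, the data pass
#' through unchanged. The automatic pick can be overridden with an explicit
#' component index.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @param n_components number of components; defaults to the channel count.
#' @param low_freq_band band (Hz) whose power fraction flags blink
#'   components. Default `c(0.5, 4)`.
#' @param kurtosis_floor minimum excess kurtosis for a blink candidate.
#'   Default 2.
#' @param min_band_fraction minimum 0.5-4 Hz power fraction for a candidate
#'   (a blink component still carries a whitened broadband floor, so its
#'   fraction sits well below 1). Default 0.4.
#' @param component explicit 1-based component index to remove, bypassing
#'   the automatic pick; `NA` (default) means automatic.
#' @param seed seed for the ICA initial rotation.
#' @return A list with `recording` (cleaned [eeg_recording()]), `removed`
#'   (component index or `NA` if none), and `components` (tibble of
#'   per-component diagnostics: `component`, `band_fraction`, `kurtosis`,
#'   `removed`), plus `sources` (components x samples matrix).
#' @export
ica_blink_removal <- function(rec, n_components = NULL,
                              low_freq_band = c(0.5, 4),
                              kurtosis_floor = 2,
                              min_band_fraction = 0.4,
                              component = NA_integer_,
                              seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L) {
    stop("blink removal by ICA requires at least 2 channels.", call. = FALSE)
  }
  if (is.null(n_components)) n_components <- n_channels(rec)
  dec <- fastica_decompose(rec$data, n_components, seed = seed)
  k <- nrow(dec$sources)
  diag_tbl <- tibble::tibble(
    component = seq_len(k),
    band_fraction = vapply(seq_len(k), function(i) {
      band_power_fraction(dec$sources[i, ], rec$fs, low_freq_band)
    }, numeric(1)),
    kurtosis = vapply(seq_len(k), function(i) {
      excess_kurtosis(dec$sources[i, ])
    }, numeric(1)))
  if (is.na(component)) {
    cand <- diag_tbl$kurtosis >= kurtosis_floor &
      diag_tbl$band_fraction >= min_band_fraction
    removed <- if (any(cand)) {
      diag_tbl$component[cand][which.max(diag_tbl$band_fraction[cand])]
    } else NA_integer_
  } else {
    if (!component %in% seq_len(k)) {
      stop("`component` index out of range.", call. = FALSE)
    }
    removed <- as.integer(component)
  }
  diag_tbl$removed <- !is.na(removed) & diag_tbl$component == removed
  if (is.na(removed)) {
    cleaned <- rec
  } else {
    S <- dec$sources
    S[removed, ] <- 0
    data <- dec$mixing %*% S + dec$center
    cleaned <- eeg_recording(data, rec$fs, rec$channel_labels, rec$schedule)
  }
  list(recording = cleaned, removed = removed, components = diag_tbl,
       sources = dec$sources)
}
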