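#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ERP result
#'
#' One row per condition and time point of the grand average, plus the
#' difference wave as condition `"difference"`.
#'
#' @param x an `erp_result`.
#' @param ... unused.
#' @return A tibble: `condition`, `time_ms`, `amplitude_uv`.
#' @method tidy erp_result
#' @export
tidy.erp_result <- function(x, ...) {
  dplyr::bind_rows(
    x$grand_average,
    dplyr::mutate(x$difference, condition = "difference",
                  .before = "time_ms"))
}

#' One-row summary of an ERP result
#'
#' @param x an `erp_result`.
#' @param search_window_ms P300 search window, milliseconds.
#' @param ... unused.
#' @return A tibble: `p300_amplitude_uv`, `p300_latency_ms`,
#'   `n_participants`, `n_excluded`.
#' @method glance erp_result
#' @export
glance.erp_result <- function(x, search_window_ms = c(250, 600), ...) {
  p <- measure_p300(x, search_window_ms)
  tibble::tibble(p300_amplitude_uv = p$amplitude_uv,
                 p300_latency_ms = p$latency_ms,
                 n_participants = x$n_participants,
                 n_excluded = x$n_excluded)
}
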