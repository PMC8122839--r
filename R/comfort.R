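# Bipolar comfort-scale scoring and the study-level comparison statistics:
# noninferiority/nonsuperiority two-sample t-tests with a margin in units of
# the pooled SD, a tie-corrected Friedman rank sum test, and the classical
# unpaired t-test.

#' Convert bipolar comfort-scale marks to numerical values
#'
#' The questionnaire has seven bipolar adjective lines with seven positions
#' each. Marks on lines 2, 4 and 6 convert directly (1 nearest the left-end
#' adjective, 7 nearest the right-end); lines 1, 3, 5 and 7 run the other
#' way, so a mark `m` converts to `8 - m`. After conversion, higher always
#' means more comfortable.
#'
#' @param marks data frame or tibble with columns `line` (1-7) and `mark`
#'   (1-7); one row per line. A bare numeric vector of seven marks (lines
#'   1..7 in order) is also accepted.
#' @param reversed_lines lines whose scale direction is reversed.
#'   Default `c(1, 3, 5, 7)`.
#' @return The input tibble with a `converted` column.
#' @export
#' @examples
#' convert_comfort_scales(c(7, 1, 7, 1, 7, 1, 7))  # every line at its best end
convert_comfort_scales <- function(marks, reversed_lines = c(1, 3, 5, 7)) {
  if (is.numeric(marks) && is.null(dim(marks))) {
    marks <- tibble::tibble(line = seq_along(marks), mark = as.numeric(marks))
  }
  marks <- tibble::as_tibble(marks)
  stopifnot(all(c("line", "mark") %in% names(marks)))
  if (!all(marks$mark %in% 1:7)) {
    stop("every mark must be an integer position in 1..7.", call. = FALSE)
  }
  dplyr::mutate(marks, converted = ifelse(.data$line %in% reversed_lines,
                                          8 - .data$mark, .data$mark))
}

#' Comfort index of one response sheet
#'
#' The linear sum of the seven converted scale values, ranging from 7 (most
#' uncomfortable) to 49 (most comfortable).
#'
#' @param response output of [convert_comfort_scales()] (or anything with a
#'   `converted` column of seven values), or a bare vector of seven raw
#'   marks which is converted first.
#' @param reversed_lines forwarded to [convert_comfort_scales()] when raw
#'   marks are given.
#' @return Integer comfort index in `[7, 49]`.
#' @export
#' @examples
#' comfort_index(c(7, 1, 7, 1, 7, 1, 7))  # 49
comfort_index <- function(response, reversed_lines = c(1, 3, 5, 7)) {
  if (is.numeric(response) && is.null(dim(response))) {
    response <- convert_comfort_scales(response, reversed_lines)
  }
  response <- tibble::as_tibble(response)
  if (!"converted" %in% names(response)) {
    stop("`response` must carry a `converted` column; run convert_comfort_scales() first.",
         call. = FALSE)
  }
  if (nrow(response) != 7L || anyNA(response$converted)) {
    stop("a complete response has exactly seven converted scale values.",
         call. = FALSE)
  }
  as.integer(sum(response$converted))
}

#' Score a sheet of comfort responses
#'
#' @param sheet tibble with columns `participant`, `device`, `line`, `mark`.
#' @param reversed_lines lines with reversed direction.
#' @return A tibble with one row per participant x device: `participant`,
#'   `device`, `comfort_index`.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_comfort_responses.tsv",
#'                     package = "earpipe")
#' sheet <- utils::read.table(path, sep = "\t", header = TRUE)
#' score_comfort_sheet(sheet)
score_comfort_sheet <- function(sheet, reversed_lines = c(1, 3, 5, 7)) {
  sheet <- tibble::as_tibble(sheet)
  stopifnot(all(c("participant", "device", "line", "mark") %in% names(sheet)))
  sheet |>
    convert_comfort_scales(reversed_lines = reversed_lines) |>
    dplyr::group_by(.data$participant, .data$device) |>
    dplyr::summarise(comfort_index = comfort_index(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
}

#' Noninferiority / nonsuperiority two-sample t-test
#'
#' One-sided two-sample t-tests on a shifted difference with margin epsilon.
#' Noninferiority tests H0: mu_a - mu_b <= -epsilon (a is worse than b by
#' more than the margin) against H1: mu_a - mu_b > -epsilon; the statistic
#' is `t = (mean(a) - mean(b) + epsilon) / SE`, with the upper-tail p-value.
#' Nonsuperiority tests H0: mu_a - mu_b >= +epsilon symmetrically, with the
#' lower-tail p-value of `t = (mean(a) - mean(b) - epsilon) / SE`. With
#' `margin = "sigma"` the margin is the pooled two-sample SD of the data.
#'
#' @param group_a,group_b numeric vectors (e.g. comfort indices per device).
#' @param margin `"sigma"` (margin = pooled SD, the default) or a
#'   nonnegative number in the units of the data.
#' @param direction `"noninferiority"` or `"nonsuperiority"`.
#' @param var_equal use the pooled-variance t (default TRUE); FALSE gives
#'   the Welch form.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `margin`, `mean_difference`.
#' @export
#' @examples
#' a <- c(40, 42, 44, 45, 41); b <- c(38, 40, 41, 43, 39)
#' noninferiority_t_test(a, b)
noninferiority_t_test <- function(group_a, group_b, margin = "sigma",
                                  direction = c("noninferiority",
                                                "nonsuperiority"),
                                  var_equal = TRUE) {
  direction <- match.arg(direction)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations.", call. = FALSE)
  }
  eps <- if (identical(margin, "sigma")) pooled_sd(group_a, group_b)
  else {
    check_nonneg_scalar(margin, "margin")
    margin
  }
  na <- length(group_a); nb <- length(group_b)
  if (var_equal) {
    sp <- pooled_sd(group_a, group_b)
    if (sp == 0 && eps > 0) {
      stop("zero pooled variance with a nonzero margin: t is degenerate.",
           call. = FALSE)
    }
    se <- sp * sqrt(1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    va <- stats::var(group_a) / na; vb <- stats::var(group_b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  d <- mean(group_a) - mean(group_b)
  if (direction == "noninferiority") {
    t <- (d + eps) / se
    p <- stats::pt(t, df, lower.tail = FALSE)
  } else {
    t <- (d - eps) / se
    p <- stats::pt(t, df, lower.tail = TRUE)
  }
  tibble::tibble(test = paste0(direction, " two-sample t"),
                 statistic = t, df = df, p_value = p,
                 margin = eps, mean_difference = d)
}

#' Friedman rank sum test with midrank tie correction
#'
#' Within-subject ranking of `k` treatments over `n` subjects (blocks), ties
#' resolved by midranks, with the standard tie-corrected chi-square
#' statistic on `k - 1` degrees of freedom. Coincides with
#' [stats::friedman.test()] on tie-free data.
#'
#' @param block_matrix numeric matrix or data frame, subjects x treatments.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 5, 9))
#' friedman_test(m)   # statistic 6, df 2
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) stop("every subject needs a value for every treatment.",
                     call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 treatments.", call. = FALSE)
  }
  ranks <- t(apply(m, 1L, rank))        # midranks within each subject
  Rj <- colSums(ranks)
  # tie correction: 1 - sum(t^3 - t) / (n k (k^2 - 1)) over tie groups
  tie_sum <- sum(apply(m, 1L, function(row) {
    tl <- table(row)
    sum(tl^3 - tl)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C == 0) {
    # every row completely tied: no evidence against exchangeability
    return(tibble::tibble(test = "Friedman rank sum", statistic = 0,
                          df = k - 1, p_value = 1))
  }
  stat <- (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
  tibble::tibble(test = "Friedman rank sum", statistic = stat, df = k - 1,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Unpaired two-sample t-test
#'
#' Classical two-sided two-sample t-test, pooled-variance by default with
#' the Welch form available; a tidy wrapper around [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors.
#' @param var_equal pooled-variance form (default TRUE).
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `mean_difference`.
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
unpaired_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations.", call. = FALSE)
  }
  fit <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(test = if (var_equal) "unpaired t (pooled)" else "unpaired t (Welch)",
                 statistic = unname(fit$statistic), df = unname(fit$parameter),
                 p_value = fit$p.value,
                 mean_difference = mean(group_a) - mean(group_b))
}
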