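test_that("scale conversion honors the reversed-line convention", {
  conv <- convert_comfort_scales(tibble::tibble(line = 1:7, mark = rep(1, 7)))
  expect_equal(conv$converted, c(7, 1, 7, 1, 7, 1, 7))
  expect_equal(convert_comfort_scales(rep(4, 7))$converted, rep(4, 7))
  expect_error(convert_comfort_scales(c(0, rep(4, 6))), "1..7")

  # involution on reversed lines: converting twice returns the raw mark
  raw <- tibble::tibble(line = 1:7, mark = c(2, 5, 7, 1, 3, 6, 4))
  once <- convert_comfort_scales(raw)
  twice <- convert_comfort_scales(
    tibble::tibble(line = once$line, mark = once$converted))
  expect_equal(twice$converted, raw$mark)
})

test_that("comfort index spans its closed range", {
  best <- tibble::tibble(line = 1:7, mark = c(1, 7, 1, 7, 1, 7, 1))
  expect_equal(comfort_index(convert_comfort_scales(best)), 49L)
  worst <- tibble::tibble(line = 1:7, mark = c(7, 1, 7, 1, 7, 1, 7))
  expect_equal(comfort_index(convert_comfort_scales(worst)), 7L)
  expect_equal(comfort_index(rep(4, 7)), 28L)
  expect_error(comfort_index(convert_comfort_scales(rep(4, 6))), "seven")
})

test_that("comfort sheets score per participant and device", {
  sheet <- tidyr::expand_grid(participant = c("p1", "p2"),
                              device = c("custom", "generic"),
                              line = 1:7) |>
    dplyr::mutate(mark = ifelse(device == "custom",
                                ifelse(line %% 2 == 1, 1, 7), 4))
  scores <- score_comfort_sheet(sheet)
  expect_equal(nrow(scores), 4)
  expect_equal(scores$comfort_index[scores$device == "custom"], c(49L, 49L))
  expect_equal(scores$comfort_index[scores$device == "generic"], c(28L, 28L))
})

test_that("noninferiority t-test matches its closed form", {
  a <- c(40, 42, 44, 45, 41)

  # zero margin on identical groups: t = 0, p = 0.5
  r0 <- noninferiority_t_test(a, a, margin = 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 0.5)

  # equal means with margin sigma-hat: t = eps / SE, p < 0.5
  r1 <- noninferiority_t_test(a, a + 0, margin = "sigma")
  sp <- sqrt(stats::var(a))               # pooled SD of two copies of a
  se <- sp * sqrt(2 / 5)
  expect_equal(r1$statistic, sp / se, tolerance = 1e-12)
  expect_lt(r1$p_value, 0.5)

  # a large favorable shift drives p below 1e-6
  big <- noninferiority_t_test(a + 50, a)
  expect_lt(big$p_value, 1e-6)

  # nonsuperiority mirrors the shifted one-sided test
  r2 <- noninferiority_t_test(a, a, margin = 2, direction = "nonsuperiority")
  expect_equal(r2$statistic, -2 / (sqrt(stats::var(a)) * sqrt(2 / 5)),
               tolerance = 1e-12)
  expect_lt(r2$p_value, 0.5)

  expect_error(noninferiority_t_test(c(1, 1), c(1, 1), margin = 1),
               "degenerate")
  expect_error(noninferiority_t_test(1, c(1, 2)), "at least 2")
})

test_that("noninferiority p agrees with a permutation oracle", {
  set.seed(8)
  a <- stats::rnorm(8, mean = 30, sd = 3)
  b <- stats::rnorm(8, mean = 29, sd = 3)
  eps <- earpipe:::pooled_sd(a, b)
  obs <- noninferiority_t_test(a, b, margin = "sigma")

  # permutation distribution of the shifted-difference statistic under H0
  # boundary (mu_a - mu_b = -eps): shift group a up by eps, then permute
  a0 <- a + (mean(b) - mean(a) - eps)   # impose the boundary exactly
  pool <- c(a0, b)
  n_perm <- 4000
  stat <- function(x, y) (mean(x) - mean(y) + eps) /
    (earpipe:::pooled_sd(x, y) * sqrt(1 / 8 + 1 / 8))
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(16, 8)
    stat(pool[idx], pool[-idx])
  }, numeric(1))
  p_perm <- mean(perm >= stat(a, b))
  expect_equal(obs$p_value, p_perm, tolerance = 0.05)
})

test_that("Friedman statistic matches hand-ranked arithmetic", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 5, 9))   # strictly ordered rows
  r <- friedman_test(m)
  expect_equal(r$statistic, 6)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, stats::pchisq(6, 2, lower.tail = FALSE))

  tied <- rbind(c(1, 1, 1), c(2, 2, 2))
  rt <- friedman_test(tied)
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 1)

  expect_error(friedman_test(rbind(c(1, NA), c(2, 3))), "every treatment")
})

test_that("Friedman agrees with stats::friedman.test on tie-free data", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(stats::rnorm(8 * 4), 8, 4)
    mine <- friedman_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("two-treatment Friedman orders p-values like the exact sign test", {
  # n = 8 subjects, no ties: the block design is determined by the number of
  # subjects m preferring treatment 1; enumerate all m
  n <- 8
  p_fried <- p_sign <- numeric(n + 1)
  for (m in 0:n) {
    mat <- cbind(1, c(rep(2, m), rep(0, n - m)))
    fr <- friedman_test(mat)
    expect_equal(fr$statistic, (2 * m - n)^2 / n)   # sign-test reduction
    p_fried[m + 1] <- fr$p_value
    p_sign[m + 1] <- min(1, 2 * stats::pbinom(min(m, n - m), n, 0.5))
  }
  expect_equal(order(p_fried), order(p_sign))
})

test_that("unpaired t-test reproduces the textbook pooled computation", {
  r <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)

  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sw <- unpaired_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$p_value, r$p_value)
})

test_that("type-I error rates are calibrated under the null", {
  set.seed(2024)
  n_rep <- 10000
  n <- 10
  # vectorized pooled two-sample t on normal null draws
  A <- matrix(stats::rnorm(n * n_rep), n)
  B <- matrix(stats::rnorm(n * n_rep), n)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  sp <- sqrt((va + vb) / 2)
  tt <- (colMeans(A) - colMeans(B)) / (sp * sqrt(2 / n))
  rate_t <- mean(abs(tt) > stats::qt(0.975, 2 * n - 2))
  expect_gte(rate_t, 0.045)
  expect_lte(rate_t, 0.055)

  # two-treatment Friedman reduces to the sign test; its null rejection rate
  # at alpha = 0.05 equals the exact binomial tail mass (conservative by
  # discreteness), computed here by enumeration as the oracle
  stat_crit <- stats::qchisq(0.95, 1)
  m <- 0:n
  reject_m <- (2 * m - n)^2 / n > stat_crit
  exact_rate <- sum(stats::dbinom(m, n, 0.5) * reject_m)
  sim_m <- stats::rbinom(n_rep, n, 0.5)
  rate_f <- mean((2 * sim_m - n)^2 / n > stat_crit)
  expect_lt(abs(rate_f - exact_rate), 0.006)
  expect_lte(rate_f, 0.05)
})
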