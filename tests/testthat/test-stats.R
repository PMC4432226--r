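test_that("Wilson intervals reproduce the printed connectivity CIs", {
  wa <- wilson_interval(15, 35, 0.90)
  expect_equal(round_half_up(c(wa$lower, wa$upper)), c(0.30, 0.57))
  wb <- wilson_interval(23, 112, 0.90)
  expect_equal(round_half_up(c(wb$lower, wb$upper)), c(0.15, 0.27))
  # k = 0: lower bound exactly zero
  expect_equal(wilson_interval(0, 17)$lower, 0)
  expect_error(wilson_interval(3, 0), ">= 1")
  expect_error(wilson_interval(5, 3), "0 <= k <= n")
})

test_that("Wilson interval equals grid inversion of the score test (n <= 50 spot set)", {
  z <- stats::qnorm(0.95)
  grid <- seq(0, 1, by = 1e-5)
  for (n in c(1, 7, 35, 50)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      w <- wilson_interval(k, n)
      ok <- abs(k / n - grid) <= z * sqrt(grid * (1 - grid) / n)
      expect_lt(abs(min(grid[ok]) - w$lower), 2e-5)
      expect_lt(abs(max(grid[ok]) - w$upper), 2e-5)
    }
  }
})

test_that("Wilson width shrinks monotonically in n at fixed k/n", {
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    w <- wilson_interval(round(0.3 * n), n)
    w$upper - w$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("interval overlap rule: disjoint means different at the (1-level)^2 bound", {
  wa <- wilson_interval(15, 35, 0.90)
  wb <- wilson_interval(23, 112, 0.90)
  ov <- interval_overlap_test(wa, wb)
  expect_true(ov$different)
  expect_equal(ov$alpha_bound, 0.01)
  expect_false(interval_overlap_test(wa, wa)$different)
  # touching endpoints count as overlap (closed intervals)
  a <- list(lower = 0.1, upper = 0.3, level = 0.9)
  b <- list(lower = 0.3, upper = 0.5, level = 0.9)
  expect_false(interval_overlap_test(a, b)$different)
})

test_that("Pearson chi-square matches the printed statistic and the algebraic shortcut", {
  tab <- rbind(c(15, 20), c(23, 89))
  r <- pearson_chi2(tab)
  expect_equal(round_half_up(r$statistic), 6.93)
  expect_lt(r$p_value, 0.01)
  # proportional rows: exactly zero
  expect_equal(pearson_chi2(rbind(c(10, 30), c(5, 15)))$statistic, 0)
  # random tables against N(ad-bc)^2 / product of margins
  set.seed(12)
  for (i in 1:25) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    short <- sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m)) / prod(colSums(m))
    expect_equal(pearson_chi2(m)$statistic, short, tolerance = 1e-9)
  }
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("90% Wilson coverage stays near nominal for the study's sample sizes", {
  # Wilson coverage oscillates with (p, n); the exact coverage is 0.8769 at
  # (0.43, 35) and 0.8968 at (0.21, 112), so empirical estimates are
  # checked against those values, not against the nominal level
  z <- stats::qnorm(0.95)
  exact_cov <- function(p, n) {
    k <- 0:n
    ph <- k / n
    denom <- 1 + z^2 / n
    center <- (ph + z^2 / (2 * n)) / denom
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / denom
    sum(stats::dbinom(k, n, p)[center - half <= p & p <= center + half])
  }
  expect_equal(exact_cov(0.43, 35), 0.8769, tolerance = 1e-4)
  expect_equal(exact_cov(0.21, 112), 0.8968, tolerance = 1e-4)
  set.seed(2024)
  for (case in list(c(0.43, 35), c(0.21, 112))) {
    p <- case[1]; n <- case[2]
    k <- rbinom(5000, n, p)
    w <- vapply(k[1:200], function(ki) {
      wi <- wilson_interval(ki, n)
      wi$lower <= p && p <= wi$upper
    }, logical(1))
    # spot agreement between the vectorized oracle and wilson_interval
    denom <- 1 + z^2 / n
    ph <- k / n
    center <- (ph + z^2 / (2 * n)) / denom
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / denom
    cover_vec <- center - half <= p & p <= center + half
    expect_identical(w, cover_vec[1:200])
    expect_equal(mean(cover_vec), exact_cov(p, n), tolerance = 0.02)
  }
})

test_that("contingency reconstruction recovers the unique printed table", {
  tab <- reconstruct_contingency(0.43, 0.21, 147, 38, chi2 = 6.93,
                                 ci_a = c(0.30, 0.57), ci_b = c(0.15, 0.27))
  expect_equal(matrix(tab, 2), rbind(c(15, 20), c(23, 89)))
  expect_equal(attr(tab, "counts")$n, c(35, 112), ignore_attr = TRUE)
  # the CI corroboration alone is already decisive
  tab2 <- reconstruct_contingency(0.43, 0.21, 147, 38,
                                  ci_a = c(0.30, 0.57), ci_b = c(0.15, 0.27))
  expect_equal(matrix(tab2, 2), rbind(c(15, 20), c(23, 89)))
  # symmetric inputs are non-unique
  expect_error(
    reconstruct_contingency(0.5, 0.5, 12, 6, chi2 = 0),
    "not unique"
  )
  # inconsistent totals
  expect_error(
    reconstruct_contingency(0.5, 0.5, 4, 6, chi2 = 0),
    "more connected"
  )
  # refuses to run with no corroborating statistic
  expect_error(reconstruct_contingency(0.43, 0.21, 147, 38), "corroborating")
})

test_that("probability_by_group tabulates counts and Wilson intervals", {
  rec <- data.frame(
    group = rep(c("FSI", "NFSI"), c(35, 112)),
    connected = c(rep(TRUE, 15), rep(FALSE, 20), rep(TRUE, 23), rep(FALSE, 89))
  )
  tab <- probability_by_group(rec)
  expect_equal(tab$k, c(15, 23))
  expect_equal(round_half_up(tab$lower), c(0.30, 0.15))
  # all-connected input
  all_c <- data.frame(group = rep("a", 5), connected = TRUE)
  expect_equal(probability_by_group(all_c)$p, 1)
  # empty day omitted: only days present in the records appear
  tc <- data.frame(day = rep(c(8, 10), c(4, 4)), connected = FALSE)
  expect_equal(probability_by_group(tc, by = "day")$day, c(8, 10))
})

test_that("timecourse peak day is recovered across seeds", {
  hit <- 0
  for (s in 1:12) {
    rec <- gen_timecourse(timecourse_params(), n_cells_per_day = 200,
                          seed = 700 + s)
    tab <- probability_by_group(rec, by = "day")
    hit <- hit + (tab$day[which.max(tab$p)] == 10)
  }
  expect_gte(hit / 12, 0.9)
})

test_that("pearson correlation handles the standard cases and degenerate input", {
  x <- 1:100
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  set.seed(5)
  big <- replicate(20, abs(pearson_correlation(rnorm(100), rnorm(100))$r) < 0.25)
  expect_gte(mean(big), 0.9)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("rank-test wrappers agree with their base equivalents", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(mann_whitney_u(x, y)$p_value,
               suppressWarnings(stats::wilcox.test(x, y))$p.value)
  g <- rep(letters[1:3], each = 10)
  v <- rnorm(30)
  expect_equal(kruskal_wallis(v, g)$p_value, stats::kruskal.test(v, factor(g))$p.value)
})
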