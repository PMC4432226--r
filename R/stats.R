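# Inferential statistics for binomial connectivity data: Wilson score
# intervals, the interval-overlap decision rule, Pearson chi-square on 2x2
# tables, reconstruction of unprinted contingency counts from printed
# proportions, per-group probability tables, and Pearson correlation.

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided score interval; for the default 90% level the normal quantile
#' is 1.644854. The Wilson interval has good small-sample coverage and is
#' the interval used for the connection-probability comparison.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level (default 0.90).
#' @return object of class `ng2_wilson`: list with `k`, `n`, `level`,
#'   `p_hat`, `lower`, `upper`.
#' @export
wilson_interval <- function(k, n, level = 0.90) {
  check_that(n >= 1, "n must be >= 1")
  check_that(k >= 0 && k <= n, "k must satisfy 0 <= k <= n")
  check_that(level > 0 && level < 1, "level must be in (0,1)")
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(
    list(k = k, n = n, level = level, p_hat = p,
         lower = max(center - half, 0), upper = min(center + half, 1)),
    class = "ng2_wilson"
  )
}

#' @export
print.ng2_wilson <- function(x, ...) {
  cat(sprintf("Wilson %d%% CI: %d/%d = %.3f, [%.4f, %.4f]\n",
              round(100 * x$level), x$k, x$n, x$p_hat, x$lower, x$upper))
  invisible(x)
}

#' Interval-overlap decision rule for two binomial proportions
#'
#' Two proportions are declared different when their confidence intervals
#' are disjoint. With independent two-sided intervals at level `1 - a`,
#' disjoint intervals under equal true proportions occur with probability
#' at most `a^2` (e.g. 0.1 x 0.1 = 1% for two 90% intervals). Intervals
#' touching at an endpoint count as overlapping (closed-interval
#' convention).
#'
#' @param ci_a,ci_b `ng2_wilson` intervals (or lists with `lower`, `upper`,
#'   `level`).
#' @return list with `different` (logical) and `alpha_bound`.
#' @export
interval_overlap_test <- function(ci_a, ci_b) {
  disjoint <- ci_a$upper < ci_b$lower || ci_b$upper < ci_a$lower
  list(
    different = disjoint,
    alpha_bound = (1 - ci_a$level) * (1 - ci_b$level)
  )
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Plain `sum((O - E)^2 / E)` with df = 1 and no continuity correction.
#'
#' @param table 2x2 numeric matrix of counts (rows: groups; columns:
#'   connected / unconnected), all margins positive.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  check_that(all(dim(m) == c(2, 2)), "table must be 2x2")
  check_that(all(m >= 0), "counts must be >= 0")
  check_that(all(rowSums(m) > 0) && all(colSums(m) > 0),
             "all margins must be positive")
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, df = 1L, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Reconstruct a 2x2 connection table from printed proportions
#'
#' Given the rounded per-group connection proportions, the total number of
#' tested pairs and the total number of connected pairs, searches
#' exhaustively over all integer splits and keeps candidates whose
#' proportions round (half-up, 2 dp) to the printed values. Candidates are
#' then disambiguated by requiring that the supplied corroborating printed
#' statistics (a chi-square value and/or per-group confidence-interval
#' bounds, all at printed rounding) are reproduced. Errors if no candidate
#' or more than one candidate survives.
#'
#' @param p_a,p_b printed proportions (2 dp) for groups A and B.
#' @param total_pairs total pairs tested (n_a + n_b).
#' @param total_connected total connected pairs (k_a + k_b).
#' @param chi2 printed chi-square value (2 dp), or NULL.
#' @param ci_a,ci_b printed interval bounds (length-2, 2 dp), or NULL.
#' @param level confidence level of the printed intervals.
#' @return 2x2 matrix: rows A, B; columns connected, unconnected. The
#'   surviving (k, n) pairs are attached as attribute `counts`.
#' @export
reconstruct_contingency <- function(p_a, p_b, total_pairs, total_connected,
                                    chi2 = NULL, ci_a = NULL, ci_b = NULL,
                                    level = 0.90) {
  check_that(total_connected <= total_pairs, "more connected than tested pairs")
  check_that(!is.null(chi2) || !is.null(ci_a) || !is.null(ci_b),
             "at least one corroborating printed statistic is required")
  cand <- list()
  for (n_a in seq_len(total_pairs - 1)) {
    n_b <- total_pairs - n_a
    k_lo <- max(0, total_connected - n_b)
    k_hi <- min(n_a, total_connected)
    if (k_lo > k_hi) next
    for (k_a in k_lo:k_hi) {
      k_b <- total_connected - k_a
      if (round_half_up(k_a / n_a) != p_a) next
      if (round_half_up(k_b / n_b) != p_b) next
      tab <- rbind(c(k_a, n_a - k_a), c(k_b, n_b - k_b))
      if (!is.null(chi2)) {
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
        if (round_half_up(pearson_chi2(tab)$statistic) != chi2) next
      }
      if (!is.null(ci_a)) {
        wa <- wilson_interval(k_a, n_a, level)
        if (any(round_half_up(c(wa$lower, wa$upper)) != ci_a)) next
      }
      if (!is.null(ci_b)) {
        wb <- wilson_interval(k_b, n_b, level)
        if (any(round_half_up(c(wb$lower, wb$upper)) != ci_b)) next
      }
      cand[[length(cand) + 1]] <- tab
    }
  }
  check_that(length(cand) >= 1, "no integer table reproduces the printed values")
  if (length(cand) > 1) {
    stop(sprintf("contingency reconstruction is not unique: %d candidates survive",
                 length(cand)), call. = FALSE)
  }
  tab <- cand[[1]]
  dimnames(tab) <- list(c("A", "B"), c("connected", "unconnected"))
  attr(tab, "counts") <- data.frame(
    group = c("A", "B"), k = tab[, 1], n = rowSums(tab)
  )
  tab
}

#' Connection-probability table by group
#'
#' Tabulates per-cell connection counts and Wilson intervals for records of
#' tested pairs, optionally crossed with a second grouping (e.g. postnatal
#' day). Groups with no records are omitted with a notice attribute.
#'
#' @param records data.frame with a logical/0-1 `connected` column and one
#'   or two grouping columns.
#' @param by character vector of grouping column names (1 or 2).
#' @param level confidence level for the Wilson intervals.
#' @return data.frame with the group columns, `k`, `n`, `p`, `lower`,
#'   `upper`.
#' @export
probability_by_group <- function(records, by = "group", level = 0.90) {
  check_that(all(by %in% names(records)), "grouping columns missing from records")
  check_that("connected" %in% names(records), "records need a 'connected' column")
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    k <- sum(sub$connected)
    n <- nrow(sub)
    w <- wilson_interval(k, n, level)
    cbind(
      sub[1, by, drop = FALSE],
      data.frame(k = k, n = n, p = k / n, lower = w$lower, upper = w$upper)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  check_that(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  check_that(length(x) >= 3, "need at least 3 complete observations")
  check_that(stats::sd(x) > 0 && stats::sd(y) > 0, "constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Mann-Whitney U test (thin wrapper)
#'
#' Generic two-group rank test used for group comparisons of real data;
#' provided for completeness of the statistical toolkit.
#'
#' @param x,y numeric samples.
#' @return list with `statistic`, `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Kruskal-Wallis test (thin wrapper)
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  ht <- stats::kruskal.test(values, factor(groups))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
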