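#' Descriptive summary of a sample
#'
#' Mean/SD and median/IQR (IQR = Q3 - Q1) with quartiles by linear
#' interpolation between order statistics (R's default type-7 quantiles).
#'
#' @param x Numeric vector (missing values dropped).
#' @return List: `n`, `mean`, `sd`, `median`, `q1`, `q3`, `iqr`.
#' @export
descriptives <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) stop("need at least one finite value", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(
    n = n,
    mean = mean(x),
    sd = if (n > 1L) stats::sd(x) else 0,
    median = q[2L],
    q1 = q[1L],
    q3 = q[3L],
    iqr = q[3L] - q[1L]
  )
}

#' Normality-routed two-group comparison
#'
#' The group-comparison convention of the analysis: Shapiro-Wilk on each
#' sample at `alpha`; if both pass, a two-sample t-test, otherwise a
#' Mann-Whitney U test. The Mann-Whitney p-value is exact (enumeration) when
#' the combined sample size is at most `exact_max_n` and there are no ties,
#' and uses the midrank normal approximation with tie and continuity
#' correction otherwise. All tests are two-tailed.
#'
#' @param x,y Numeric samples (missing values dropped).
#' @param alpha Normality-test significance level (default 0.05).
#' @param exact_max_n Largest combined n for exact Mann-Whitney enumeration.
#' @return An object of class `group_comparison`: `route` (`"t_test"`,
#'   `"mann_whitney"` or `"none"` when either n < 3), `statistic`, `p_value`,
#'   `shapiro_p` (length 2), and per-sample `descriptives`.
#' @export
compare_groups <- function(x, y, alpha = 0.05, exact_max_n = 20L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  desc <- list(x = descriptives(x), y = descriptives(y))
  if (length(x) < 3L || length(y) < 3L) {
    return(structure(list(
      route = "none", statistic = NA_real_, p_value = NA_real_,
      shapiro_p = c(NA_real_, NA_real_), descriptives = desc
    ), class = "group_comparison"))
  }
  sw <- function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  shapiro_p <- c(sw(x), sw(y))
  if (all(shapiro_p > alpha)) {
    ht <- stats::t.test(x, y)
    route <- "t_test"
  } else {
    mw <- mann_whitney(x, y, exact_max_n = exact_max_n)
    ht <- list(statistic = mw$statistic, p.value = mw$p_value)
    route <- "mann_whitney"
  }
  structure(list(
    route = route,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    shapiro_p = shapiro_p,
    descriptives = desc
  ), class = "group_comparison")
}

#' Mann-Whitney U test with exact/approximate routing
#'
#' The rank-sum comparison underlying [compare_groups]: the exact two-tailed
#' p-value by enumeration when the combined sample size is at most
#' `exact_max_n` and there are no ties, otherwise the midrank normal
#' approximation with tie and continuity correction. The statistic is the
#' Mann-Whitney U of the first sample.
#'
#' @inheritParams compare_groups
#' @return List: `statistic` (U), `p_value`, `exact` (logical).
#' @export
mann_whitney <- function(x, y, exact_max_n = 20L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max_n && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = !use_exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = use_exact)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> route=%s, statistic=%.4g, p=%.4g\n",
              x$route, x$statistic, x$p_value))
  invisible(x)
}

as_table2x2 <- function(t) {
  if (is.matrix(t) || is.table(t)) {
    if (!all(dim(t) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
    t <- as.vector(t(as.matrix(t)))  # row-wise: a, b, c, d
  }
  if (length(t) != 4L || any(!is.finite(t)) || any(t < 0) || any(t != round(t))) {
    stop("need 4 non-negative integer counts (a, b, c, d)", call. = FALSE)
  }
  as.numeric(t)
}

#' Build a 2x2 contingency table
#'
#' Row convention: rows are subgroups (e.g. painful / painless), columns are
#' outcome classes (e.g. abnormal / normal); `a, b` is the first row.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param rows,cols Optional dimnames.
#' @return A 2x2 integer matrix.
#' @export
contingency2x2 <- function(a, b, c, d, rows = c("group1", "group2"),
                           cols = c("abnormal", "normal")) {
  m <- matrix(as.integer(c(a, b, c, d)), nrow = 2L, byrow = TRUE,
              dimnames = list(rows, cols))
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  m
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' `chi2 = n * (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with the
#' continuity correction floored at zero when `|ad - bc| <= n/2`; p-value on
#' 1 degree of freedom.
#'
#' @param t A 2x2 matrix/table or a length-4 vector `(a, b, c, d)` read
#'   row-wise.
#' @return List: `statistic`, `p_value`, `df = 1`, `flagged` (TRUE with `NA`
#'   statistic when any margin is zero).
#' @examples
#' chi2_yates(c(16, 3, 15, 15))$statistic  # 4.48
#' @export
chi2_yates <- function(t) {
  v <- as_table2x2(t)
  a <- v[1L]; b <- v[2L]; cc <- v[3L]; d <- v[4L]
  n <- a + b + cc + d
  if (n <= 0) stop("table is empty", call. = FALSE)
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L, flagged = TRUE))
  }
  num <- max(abs(a * d - b * cc) - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    df = 1L,
    flagged = FALSE
  )
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad / bc`; `CI = exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero the Haldane-Anscombe correction (+0.5 to every
#' cell) is applied and the estimate is flagged.
#'
#' @inheritParams chi2_yates
#' @return List: `or`, `ci` (length 2), `corrected` (logical).
#' @examples
#' odds_ratio(c(16, 3, 15, 15))$or  # 5.33
#' @export
odds_ratio <- function(t) {
  v <- as_table2x2(t)
  corrected <- any(v == 0)
  if (corrected) v <- v + 0.5
  a <- v[1L]; b <- v[2L]; cc <- v[3L]; d <- v[4L]
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  half <- stats::qnorm(0.975) * se
  list(
    or = or,
    ci = exp(log(or) + c(-half, half)),
    corrected = corrected
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-tailed exact p-value by full hypergeometric enumeration: the sum of
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table.
#'
#' @inheritParams chi2_yates
#' @return List: `p_value`.
#' @export
fisher_exact <- function(t) {
  v <- as_table2x2(t)
  a <- v[1L]; b <- v[2L]; cc <- v[3L]; d <- v[4L]
  m1 <- a + b
  m2 <- cc + d
  k <- a + cc
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  list(p_value = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
}

#' Spearman rank correlation
#'
#' Spearman's rho with midranks for ties and a two-tailed p-value.
#'
#' @param x,y Paired numeric vectors, n >= 4 complete pairs.
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = !ties))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
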