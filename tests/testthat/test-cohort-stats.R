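test_that("Yates chi-square reproduces the published worked example and floors", {
  res <- chi2_yates(c(16, 3, 15, 15))
  expect_equal(round(res$statistic, 2), 4.48)
  expect_lt(res$p_value, 0.05)
  # cross-check against the standard library implementation
  ref <- suppressWarnings(chisq.test(contingency2x2(16, 3, 15, 15), correct = TRUE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  expect_equal(chi2_yates(c(10, 10, 10, 10))$statistic, 0)
  # |ad - bc| = 2 <= n/2 = 4: correction floor
  expect_equal(chi2_yates(c(2, 2, 2, 2))$statistic, 0)

  degenerate <- chi2_yates(c(0, 0, 5, 5))
  expect_true(degenerate$flagged)
  expect_true(is.na(degenerate$statistic))
})

test_that("odds ratio and Woolf interval behave on worked and degenerate tables", {
  res <- odds_ratio(c(16, 3, 15, 15))
  expect_equal(round(res$or, 2), 5.33)
  expect_false(res$corrected)
  expect_true(res$ci[1] < res$or && res$or < res$ci[2])

  expect_equal(odds_ratio(c(10, 10, 10, 10))$or, 1.0)

  corrected <- odds_ratio(c(1, 0, 1, 1))
  expect_true(corrected$corrected)
  expect_equal(corrected$or, 3.0)  # (1.5*1.5)/(0.5*1.5)

  # CI width shrinks as all cells scale up
  w1 <- diff(log(odds_ratio(c(8, 4, 6, 10))$ci))
  w4 <- diff(log(odds_ratio(4 * c(8, 4, 6, 10))$ci))
  expect_lt(w4, w1)
})

test_that("chi-square and odds ratio are invariant to simultaneous label swaps", {
  tab <- contingency2x2(16, 3, 15, 15)
  swapped <- tab[2:1, 2:1]
  expect_equal(chi2_yates(swapped)$statistic, chi2_yates(tab)$statistic)
  expect_equal(odds_ratio(swapped)$or, odds_ratio(tab)$or)
  expect_equal(fisher_exact(swapped)$p_value, fisher_exact(tab)$p_value)
})

test_that("Fisher exact p matches enumeration and the reference implementation", {
  # (5,0,0,5): only the two perfectly separated tables are as extreme
  res <- fisher_exact(c(5, 0, 0, 5))
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  expect_equal(fisher_exact(c(10, 10, 10, 10))$p_value, 1)

  for (tab in list(c(3, 7, 8, 2), c(1, 9, 5, 5), c(16, 3, 15, 15))) {
    expect_equal(fisher_exact(tab)$p_value,
                 fisher.test(contingency2x2(tab[1], tab[2], tab[3], tab[4]))$p.value,
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("Spearman rho reproduces the hand-computed rank formula", {
  res <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$rho, 0.8)  # 1 - 6*2/(4*15)

  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_cor(1:6, rev(1:6))$rho, -1)
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("descriptives use type-7 quantiles and IQR = Q3 - Q1", {
  d <- descriptives(c(1, 2, 3, 4))
  expect_equal(d$median, 2.5)
  expect_equal(d$q1, 1.75)
  expect_equal(d$q3, 3.25)
  expect_equal(d$iqr, 1.5)

  expect_equal(descriptives(rep(4, 5))$sd, 0)
  expect_equal(descriptives(rep(4, 5))$iqr, 0)
  one <- descriptives(7)
  expect_equal(one$median, 7)
  expect_equal(one$iqr, 0)
})

test_that("Mann-Whitney produces exact enumerated p-values for small samples", {
  # complete separation of two small samples: U = 0, exact two-tailed p = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(mw$exact)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$p_value, mw_exact_enum(c(1, 2, 3), c(4, 5, 6)))

  # identical tied samples: symmetric null, midrank approximation, p = 1
  res_id <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_false(res_id$exact)
  expect_equal(res_id$p_value, 1)
})

test_that("compare_groups routes by per-sample normality", {

  # two clean normal samples route to the t-test
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30, 0.2)
  res_t <- compare_groups(x, y)
  expect_equal(res_t$route, "t_test")
  expect_true(all(res_t$shapiro_p > 0.05))

  # a heavily skewed sample routes to Mann-Whitney
  set.seed(6)
  res_mw <- compare_groups(rexp(30), rnorm(30, 1))
  expect_equal(res_mw$route, "mann_whitney")

  # undersized sample: descriptives only
  res_none <- compare_groups(c(1, 2), c(3, 4, 5))
  expect_equal(res_none$route, "none")
  expect_true(is.na(res_none$p_value))
})

test_that("exact and normal-approximation MW p-values agree for moderate n", {
  set.seed(33)
  for (i in 1:20) {
    x <- runif(15)
    y <- runif(15, 0.15)
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    p_norm <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("type-I error of the routed comparison is near nominal on null data", {
  set.seed(12)
  n_sim <- 800
  rej <- 0L
  for (i in seq_len(n_sim)) {
    r <- compare_groups(rnorm(20), rnorm(20))
    if (r$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_sim
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
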