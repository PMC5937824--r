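test_that("paired t from summary moments matches hand computation and the study table", {
  # published depression comparison: t(179) printed as 3.61
  dep <- paired_t_from_summary(4.82, 5.47, 6.76, 5.78, r_ab = 0.18, n = 180)
  expect_equal(dep$t, 3.61, tolerance = 0.005)
  expect_equal(dep$df, 179L)
  expect_lt(dep$p, 0.001)
  # total FertiQoL comparison: |t| printed as 4.09 (females score lower)
  qol <- paired_t_from_summary(72.89, 15.94, 67.36, 16.11, r_ab = 0.36, n = 180)
  expect_equal(abs(qol$t), 4.09, tolerance = 0.005)
  expect_lt(qol$t, 0)

  eq <- paired_t_from_summary(3, 1, 3, 2, r_ab = 0.5, n = 20)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("paired t from raw vectors equals the differences-based hand result", {
  # differences (1, 1, 2, 2): mean 1.5, sd 0.5774, t = 5.196 on 3 df
  res <- paired_t_raw(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(res$t, 1.5 / (sd(c(1, 1, 2, 2)) / 2), tolerance = 1e-12)
  expect_equal(res$t, 5.196, tolerance = 1e-3)
  expect_equal(res$df, 3L)

  expect_equal(paired_t_raw(c(1, 2, 3), c(1, 2, 3))$t, 0)
  deg <- paired_t_raw(rep(0, 4), rep(1, 4))
  expect_true(deg$infinite_t)
  expect_equal(deg$sd_diff, 0)
})

test_that("raw and summary paired-t routes agree, and both match t.test", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    a <- rnorm(n, 10, 2)
    b <- a * 0.5 + rnorm(n, 11, 1.5)
    raw <- paired_t_raw(a, b)
    summ <- paired_t_from_summary(mean(a), sd(a), mean(b), sd(b), cor(a, b), n)
    expect_equal(raw$t, summ$t, tolerance = 1e-12)
    expect_equal(raw$p, summ$p, tolerance = 1e-12)
    oracle <- stats::t.test(b, a, paired = TRUE)
    expect_equal(raw$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(raw$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("McNemar statistic follows the discordant-count formula", {
  expect_equal(mcnemar_test(7, 7)$chi_square, 0)
  expect_equal(mcnemar_test(7, 7)$p, 1)
  expect_equal(mcnemar_test(10, 0)$chi_square, 10)
  zero <- mcnemar_test(0, 0)
  expect_equal(zero$chi_square, 0)
  expect_equal(zero$p, 1)
  # swapping the discordant cells leaves the uncorrected test unchanged
  expect_equal(mcnemar_test(3, 9)$chi_square, mcnemar_test(9, 3)$chi_square)
  expect_equal(mcnemar_test(3, 9)$p, mcnemar_test(9, 3)$p)
  # continuity correction and floor at zero
  expect_equal(mcnemar_test(6, 5, continuity = TRUE)$chi_square, 0)
  expect_equal(mcnemar_test(10, 2, continuity = TRUE)$chi_square, 49 / 12)
  expect_error(mcnemar_test(-1, 2), class = "dyadkit_error_invalid_argument")
})

test_that("McNemar agrees with the stats-package contingency-table oracle", {
  tab <- matrix(c(20, 9, 3, 12), 2)
  oracle <- stats::mcnemar.test(tab, correct = FALSE)
  ours <- mcnemar_test(tab[1, 2], tab[2, 1])
  expect_equal(ours$chi_square, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
})

test_that("correlation report matches cor.test and annotates stars monotonically", {
  set.seed(5)
  d <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  d$b <- d$b + 0.8 * d$a
  rep <- correlation_report(d, c("a", "b", "c"))
  oracle <- stats::cor.test(d$a, d$b)
  expect_equal(rep$r["a", "b"], unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(rep$p["a", "b"], oracle$p.value, tolerance = 1e-12)
  expect_equal(rep$p, t(rep$p))

  # exact linear dependence
  d2 <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  rep2 <- correlation_report(d2, c("x", "y"))
  expect_equal(rep2$r["x", "y"], 1)
  expect_lt(rep2$p["x", "y"], 1e-10)
  expect_equal(rep2$stars["x", "y"], "***")

  # p-values are invariant to rescaling of the variables
  d3 <- dplyr::mutate(d, a = a * 100, c = c / 7)
  rep3 <- correlation_report(d3, c("a", "b", "c"))
  expect_equal(rep3$p, rep$p, tolerance = 1e-12)

  expect_error(correlation_report(tibble::tibble(a = rep(1, 5), b = 1:5), c("a", "b")),
               class = "dyadkit_error_zero_variance")
})

test_that("summary-based correlation report reproduces the published star pattern", {
  rep <- correlation_report_from_summary(infertile_couples_moments("total"))
  expect_equal(rep$r["depression_male", "fertiqol_total_male"], -0.61)
  expect_equal(rep$stars["depression_male", "fertiqol_total_male"], "***")
  expect_equal(rep$stars["depression_male", "depression_female"], "*")
  long <- tidy(rep)
  expect_equal(nrow(long), choose(4, 2))
  expect_true(all(abs(long$r) <= 1))
})

test_that("Cronbach's alpha follows the variance decomposition", {
  # identical items -> alpha = 1
  x <- rnorm(15)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # two exactly uncorrelated equal-variance items -> alpha = 0
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(cronbach_alpha(cbind(a, b)), 0)
  # 3-item hand matrix against direct variance arithmetic
  m <- cbind(c(2, 4, 4, 1), c(3, 4, 5, 2), c(1, 5, 4, 1))
  k <- 3
  direct <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), direct, tolerance = 1e-12)
  expect_error(cronbach_alpha(cbind(a)), class = "dyadkit_error_invalid_argument")
  expect_error(cronbach_alpha(cbind(c(1, 1), c(2, 2))),
               class = "dyadkit_error_zero_variance")
})
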