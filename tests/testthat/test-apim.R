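test_that("model-implied covariance follows the path algebra", {
  base <- list(a_m = 0, a_f = 0, p_mf = 0, p_fm = 0, phi = diag(2), psi = diag(2))
  expect_equal(model_implied_sigma(base), diag(4))

  p2 <- base
  p2$a_m <- 1
  sig <- model_implied_sigma(p2)
  expect_equal(sig[3, 3], 2)   # var(Y_m) = a_m^2 phi11 + psi11
  expect_equal(sig[1, 3], 1)   # cov(X_m, Y_m) = a_m phi11
  expect_equal(sig, t(sig))

  # a saturated fit's implied covariance reproduces the sample covariance
  fit <- fit_apim(random_dyad_table(60, seed = 2), apim_spec(y_var = "qol"), se = FALSE)
  expect_lt(max(abs(fit$sigma - fit$S)), 1e-8)
  expect_lt(fit$chi_square, 1e-6)
  expect_equal(fit$df, 0L)
})

test_that("the ML discrepancy is zero at equality and positive elsewhere", {
  s <- matrix(c(4, 1, 1, 3), 2)
  expect_equal(f_ml(s, s), 0)
  expect_equal(f_ml(diag(2), diag(c(2, 2))), log(4) + 1 - 2, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    a <- matrix(rnorm(9), 3); S <- crossprod(a) + diag(3)
    b <- matrix(rnorm(9), 3); sig <- crossprod(b) + diag(3)
    expect_gt(f_ml(S, sig), 0)
  }
  expect_error(f_ml(diag(2), matrix(c(1, 2, 2, 1), 2)),
               class = "dyadkit_error_not_positive_definite")
})

test_that("saturated APIM slopes equal independent per-equation OLS slopes", {
  spec <- apim_spec(y_var = "qol")
  for (seed in 1:10) {
    tab <- random_dyad_table(n = 40, seed = seed)
    fit <- fit_apim(tab, spec, se = FALSE)
    oracle <- ols_apim_slopes(tab)
    expect_equal(fit$params$a_m, oracle[["actor_m"]], tolerance = 1e-8)
    expect_equal(fit$params$p_mf, oracle[["partner_mf"]], tolerance = 1e-8)
    expect_equal(fit$params$a_f, oracle[["actor_f"]], tolerance = 1e-8)
    expect_equal(fit$params$p_fm, oracle[["partner_fm"]], tolerance = 1e-8)
  }
})

test_that("standardized solution on the study moments matches the partial-regression oracle", {
  m <- infertile_couples_moments("total")
  fit <- fit_apim(m, apim_spec(y_var = "fertiqol_total"))
  oracle <- std_beta_oracle(m$correlations)
  paths <- tidy(fit)
  for (pth in names(oracle)) {
    expect_equal(paths$std_estimate[paths$path == pth], unname(oracle[[pth]]),
                 tolerance = 1e-10)
  }
  # beta = slope * sd(x) / sd(y) round-trip on the male actor path
  expect_equal(paths$std_estimate[paths$path == "actor_m"],
               fit$params$a_m * m$sds[["depression_male"]] / m$sds[["fertiqol_total_male"]],
               tolerance = 1e-10)
  # both actor effects are strongly significant (|z| > 9 on either scale)
  expect_gt(abs(paths$std_z[paths$path == "actor_m"]), 9)
  expect_gt(abs(paths$z[paths$path == "actor_f"]), 9)
})

test_that("zero predictor-outcome covariance gives zero slopes and psi = outcome covariance", {
  vars <- c("depression_male", "depression_female", "qol_male", "qol_female")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.3
  r[3, 4] <- r[4, 3] <- 0.5
  m <- moment_summary(vars, rep(0, 4), c(2, 3, 4, 5), r, n = 50)
  fit <- fit_apim(m, apim_spec(y_var = "qol"))
  expect_equal(fit$params$a_m, 0, tolerance = 1e-12)
  expect_equal(fit$params$p_mf, 0, tolerance = 1e-12)
  expect_equal(unname(fit$params$psi), unname(covariance_from_summary(m)[3:4, 3:4]),
               tolerance = 1e-10)
  expect_equal(fit$paths$z[fit$paths$path == "actor_m"], 0, tolerance = 1e-8)
  expect_equal(fit$paths$p[fit$paths$path == "actor_m"], 1, tolerance = 1e-6)
})

test_that("rescaling a predictor rescales its slopes and nothing standardized", {
  tab <- random_dyad_table(n = 60, seed = 9)
  spec <- apim_spec(y_var = "qol")
  fit <- fit_apim(tab, spec)
  tab2 <- dplyr::mutate(tab, depression_male = depression_male * 10)
  fit2 <- fit_apim(tab2, spec)
  expect_equal(fit2$params$a_m, fit$params$a_m / 10, tolerance = 1e-10)
  expect_equal(fit2$params$p_fm, fit$params$p_fm / 10, tolerance = 1e-10)
  expect_equal(fit2$paths$std_estimate, fit$paths$std_estimate, tolerance = 1e-8)
  expect_equal(fit2$paths$z, fit$paths$z, tolerance = 1e-6)
  expect_equal(fit2$chi_square, fit$chi_square, tolerance = 1e-8)
})

test_that("swapping role labels swaps the role-specific parameters", {
  tab <- random_dyad_table(n = 45, seed = 13)
  fit <- fit_apim(tab, apim_spec(y_var = "qol"), se = FALSE)
  fit_sw <- fit_apim(tab, apim_spec(y_var = "qol", roles = c("female", "male")),
                     se = FALSE)
  expect_equal(fit_sw$params$a_m, fit$params$a_f, tolerance = 1e-10)
  expect_equal(fit_sw$params$a_f, fit$params$a_m, tolerance = 1e-10)
  expect_equal(fit_sw$params$p_mf, fit$params$p_fm, tolerance = 1e-10)
  expect_equal(fit_sw$params$p_fm, fit$params$p_mf, tolerance = 1e-10)
  expect_equal(unname(fit_sw$params$phi), unname(fit$params$phi[2:1, 2:1]),
               tolerance = 1e-10)
  expect_equal(unname(fit_sw$params$psi), unname(fit$params$psi[2:1, 2:1]),
               tolerance = 1e-10)
})

test_that("collinear predictors are an explicit failure", {
  tab <- random_dyad_table(n = 30, seed = 4)
  tab$depression_female <- 2 * tab$depression_male
  expect_error(fit_apim(tab, apim_spec(y_var = "qol")),
               class = "dyadkit_error_collinear")
})

test_that("reported SEs track the Monte-Carlo sampling SD of the estimates", {
  cfg <- simulation_config(
    n_dyads = 2000,
    mu_x = c(0, 0),
    phi = matrix(c(1, 0.3, 0.3, 1.2), 2),
    slopes = c(a_m = -0.6, a_f = -0.5, p_mf = -0.15, p_fm = -0.1),
    psi = matrix(c(0.8, 0.25, 0.25, 0.9), 2)
  )
  spec <- apim_spec(y_var = "qol")
  reps <- 500
  est <- matrix(NA_real_, reps, 4)
  ses <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    fit <- fit_apim(simulate_dyads(cfg, seed = 5000 + r), spec, se = TRUE)
    est[r, ] <- fit$paths$estimate
    ses[r, ] <- fit$paths$se
  }
  ratio <- colMeans(ses) / apply(est, 2, sd)
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})

test_that("wald_tests and standardized_solution demand a fit with SEs", {
  fit <- fit_apim(random_dyad_table(30, seed = 6), apim_spec(y_var = "qol"), se = FALSE)
  expect_error(wald_tests(fit), class = "dyadkit_error_invalid_argument")
  fit2 <- fit_apim(random_dyad_table(30, seed = 6), apim_spec(y_var = "qol"))
  w <- wald_tests(fit2)
  expect_true(all(w$se > 0))
  std <- standardized_solution(fit2)
  expect_equal(std$std_estimate, fit2$paths$std_estimate)
})
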