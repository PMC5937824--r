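study_spec <- apim_spec(y_var = "fertiqol_total")

test_that("a non-binding constraint leaves the fit saturated", {
  params <- list(a_m = -1.5, a_f = -1.5, p_mf = -0.4, p_fm = -0.4,
                 phi = matrix(c(30, 5, 5, 33), 2),
                 psi = matrix(c(160, 40, 40, 170), 2))
  m <- summary_from_params(params)
  unc <- fit_apim(m, apim_spec(y_var = "qol"), se = FALSE)
  for (cs in list(constraint_spec("actor_equal"), constraint_spec("partner_equal"))) {
    con <- fit_constrained(m, apim_spec(y_var = "qol"), cs, se = FALSE)
    expect_true(con$converged)
    res <- chisq_difference(con, unc)
    expect_lt(res$chi_sq_diff, 1e-5)
    expect_gt(res$p, 0.99)
    expect_equal(res$df_diff, 1L)
  }
})

test_that("constrained discrepancy never beats the saturated one", {
  spec <- apim_spec(y_var = "qol")
  kinds <- list(constraint_spec("actor_equal"),
                constraint_spec("partner_equal"),
                constraint_spec("actor_eq_partner", role = "m"),
                constraint_spec("actor_eq_partner", role = "f"))
  for (seed in 1:5) {
    tab <- random_dyad_table(n = 60, seed = 100 + seed)
    unc <- fit_apim(tab, spec, se = FALSE)
    for (cs in kinds) {
      con <- fit_constrained(tab, spec, cs, se = FALSE)
      expect_gte(con$f_ml, unc$f_ml - 1e-10)
      expect_gte(chisq_difference(con, unc)$chi_sq_diff, 0)
    }
  }
})

test_that("chi-square difference vanishes continuously as the constraint stops binding", {
  base <- list(a_m = -1.2, p_mf = -0.3, p_fm = -0.35,
               phi = matrix(c(25, 6, 6, 30), 2),
               psi = matrix(c(120, 30, 30, 140), 2))
  gaps <- c(0.6, 0.3, 0.1, 0)
  chis <- vapply(gaps, function(g) {
    params <- c(base, list(a_f = base$a_m + g))
    m <- summary_from_params(params[c("a_m", "a_f", "p_mf", "p_fm", "phi", "psi")])
    con <- fit_constrained(m, apim_spec(y_var = "qol"),
                           constraint_spec("actor_equal"), se = FALSE)
    unc <- fit_apim(m, apim_spec(y_var = "qol"), se = FALSE)
    chisq_difference(con, unc)$chi_sq_diff
  }, numeric(1))
  expect_true(all(diff(chis) < 0))
  expect_lt(chis[length(chis)], 1e-6)
})

test_that("constrained estimates recover a shared slope planted in the population", {
  cfg <- simulation_config(
    n_dyads = 1e5,
    mu_x = c(0, 0),
    phi = matrix(c(1, 0.2, 0.2, 1.4), 2),
    slopes = c(a_m = -0.8, a_f = -0.8, p_mf = -0.2, p_fm = -0.3),
    psi = matrix(c(1, 0.3, 0.3, 1.2), 2)
  )
  tab <- simulate_dyads(cfg, seed = 99)
  con <- fit_constrained(tab, apim_spec(y_var = "qol"),
                         constraint_spec("actor_equal"), se = FALSE)
  expect_true(con$converged)
  expect_equal(con$params$a_m, con$params$a_f)
  expect_equal(con$params$a_m, -0.8, tolerance = 0.02)
  unc <- fit_apim(tab, apim_spec(y_var = "qol"), se = FALSE)
  expect_lt(chisq_difference(con, unc)$chi_sq_diff, 6)
})

test_that("standardized-scale constraints are invariant to per-variable rescaling", {
  tab <- random_dyad_table(n = 80, seed = 21)
  spec <- apim_spec(y_var = "qol")
  scaled <- dplyr::mutate(tab,
                          depression_male = depression_male * 3,
                          depression_female = depression_female / 2,
                          qol_male = qol_male * 0.4,
                          qol_female = qol_female * 5)
  for (kind in c("actor_equal", "partner_equal")) {
    cs <- constraint_spec(kind, scale = "standardized")
    base <- chisq_difference(fit_constrained(tab, spec, cs, se = FALSE),
                             fit_apim(tab, spec, se = FALSE))
    resc <- chisq_difference(fit_constrained(scaled, spec, cs, se = FALSE),
                             fit_apim(scaled, spec, se = FALSE))
    expect_equal(resc$chi_sq_diff, base$chi_sq_diff, tolerance = 1e-5)
  }
})

test_that("unstandardized constraints tolerate only block-common rescaling", {
  tab <- random_dyad_table(n = 80, seed = 22)
  spec <- apim_spec(y_var = "qol")
  cs <- constraint_spec("actor_equal")
  base <- chisq_difference(fit_constrained(tab, spec, cs, se = FALSE),
                           fit_apim(tab, spec, se = FALSE))
  # common rescale of both predictors and, separately, both outcomes: invariant
  common <- dplyr::mutate(tab,
                          depression_male = depression_male * 2.5,
                          depression_female = depression_female * 2.5,
                          qol_male = qol_male * 0.3,
                          qol_female = qol_female * 0.3)
  resc <- chisq_difference(fit_constrained(common, spec, cs, se = FALSE),
                           fit_apim(common, spec, se = FALSE))
  expect_equal(resc$chi_sq_diff, base$chi_sq_diff, tolerance = 1e-5)
  # asymmetric predictor rescale changes the unstandardized test
  uneven <- dplyr::mutate(tab, depression_male = depression_male * 4)
  resc2 <- chisq_difference(fit_constrained(uneven, spec, cs, se = FALSE),
                            fit_apim(uneven, spec, se = FALSE))
  expect_gt(abs(resc2$chi_sq_diff - base$chi_sq_diff), 1e-3)
})

test_that("mismatched fits are rejected as non-nested", {
  tab1 <- random_dyad_table(n = 40, seed = 31)
  tab2 <- random_dyad_table(n = 40, seed = 32)
  spec <- apim_spec(y_var = "qol")
  con <- fit_constrained(tab1, spec, constraint_spec("actor_equal"), se = FALSE)
  unc2 <- fit_apim(tab2, spec, se = FALSE)
  expect_error(chisq_difference(con, unc2), class = "dyadkit_error_non_nested")
  unc_n <- fit_apim(tab1, apim_spec(y_var = "qol", multiplier = "n"), se = FALSE)
  expect_error(chisq_difference(con, unc_n), class = "dyadkit_error_non_nested")
})

test_that("the four study equality tests run in fixed order with honest labels", {
  res <- run_all_equality_tests(infertile_couples_moments("total"), study_spec)
  expect_equal(res$constraint,
               c("actor_equal", "partner_equal", "actor_eq_partner", "actor_eq_partner"))
  expect_equal(res$role, c(NA, NA, "m", "f"))
  expect_true(all(res$converged))
  expect_true(all(res$df_diff == 1L))
  small <- tibble::tibble(dyad_id = 1:4,
                          depression_male = rnorm(4), depression_female = rnorm(4),
                          fertiqol_total_male = rnorm(4), fertiqol_total_female = rnorm(4))
  expect_error(run_all_equality_tests(small, study_spec),
               class = "dyadkit_error_insufficient_data")
})
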