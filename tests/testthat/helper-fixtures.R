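# Programmatic fixtures shared across test files.

phq9_df <- function(values) {
  stopifnot(length(values) == 9)
  tibble::as_tibble(as.list(stats::setNames(values, paste0("phq9_", 1:9))))
}

fertiqol_df <- function(values) {
  stopifnot(length(values) == 24)
  cols <- unlist(fertiqol_core_items(), use.names = FALSE)
  tibble::as_tibble(as.list(stats::setNames(values, cols)))
}

# A small wide dyad table drawn from the forward model.
random_dyad_table <- function(n = 50, seed = 1) {
  cfg <- simulation_config(
    n_dyads = n,
    mu_x = c(5, 7),
    phi = matrix(c(4, 1, 1, 6), 2),
    slopes = c(a_m = -1.2, a_f = -0.8, p_mf = -0.3, p_fm = 0.4),
    psi = matrix(c(9, 2, 2, 12), 2)
  )
  simulate_dyads(cfg, seed = seed)
}

# A random valid moment summary over p variables.
random_moment_summary <- function(p = 4, n = 40, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  s <- crossprod(a) + diag(p)
  r <- stats::cov2cor(s)
  moment_summary(paste0("v", seq_len(p)), means = rnorm(p, 10),
                 sds = sqrt(diag(s)), correlations = r, n = n)
}

# Moment summary whose covariance equals the model-implied covariance of
# given APIM parameters exactly (used to plant known truth in a "sample").
summary_from_params <- function(params, n = 180,
                                vars = c("depression_male", "depression_female",
                                         "qol_male", "qol_female")) {
  sigma <- model_implied_sigma(params)
  moment_summary(vars, means = rep(0, 4), sds = sqrt(diag(sigma)),
                 correlations = stats::cov2cor(sigma), n = n)
}

# Independent per-equation OLS oracle for the saturated APIM slopes.
ols_apim_slopes <- function(data, x_var = "depression", y_var = "qol",
                            roles = c("male", "female")) {
  xm <- data[[paste(x_var, roles[1], sep = "_")]]
  xf <- data[[paste(x_var, roles[2], sep = "_")]]
  ym <- data[[paste(y_var, roles[1], sep = "_")]]
  yf <- data[[paste(y_var, roles[2], sep = "_")]]
  fm <- stats::lm(ym ~ xm + xf)
  ff <- stats::lm(yf ~ xf + xm)
  c(actor_m = unname(stats::coef(fm)["xm"]),
    partner_mf = unname(stats::coef(fm)["xf"]),
    actor_f = unname(stats::coef(ff)["xf"]),
    partner_fm = unname(stats::coef(ff)["xm"]))
}

# Standardized-path oracle from a correlation matrix over
# (x_m, x_f, y_m, y_f): partial-regression formulas.
std_beta_oracle <- function(r) {
  rxx <- r[1, 2]
  den <- 1 - rxx^2
  c(actor_m = (r[3, 1] - r[3, 2] * rxx) / den,
    partner_mf = (r[3, 2] - r[3, 1] * rxx) / den,
    partner_fm = (r[4, 1] - r[4, 2] * rxx) / den,
    actor_f = (r[4, 2] - r[4, 1] * rxx) / den)
}
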