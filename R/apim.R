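# Actor-Partner Interdependence Model (APIM) for distinguishable dyads,
# estimated by maximum-likelihood covariance-structure analysis.
#
# Structural equations (no intercepts; the analysis is covariance-only):
#   Y_m = a_m  X_m + p_mf X_f + E_m
#   Y_f = a_f  X_f + p_fm X_m + E_f
# with exogenous covariance phi = Cov(X_m, X_f) (the "compositional"
# similarity of partners) and residual covariance psi = Cov(E_m, E_f)
# (non-independence beyond what the paths explain). The unconstrained model
# is saturated: its 10 parameters exactly reproduce the 10 moments of the
# 4 x 4 covariance matrix, so chi-square = 0 on 0 df and the estimates have
# a closed form (each outcome regressed on both predictors).

apim_path_labels <- function(roles) {
  tibble(
    path = c("actor_m", "partner_mf", "partner_fm", "actor_f"),
    label = c(
      sprintf("actor: %s depression -> %s outcome", roles[1], roles[1]),
      sprintf("partner: %s predictor -> %s outcome", roles[2], roles[1]),
      sprintf("partner: %s predictor -> %s outcome", roles[1], roles[2]),
      sprintf("actor: %s depression -> %s outcome", roles[2], roles[2])
    )
  )
}

#' Specify an APIM analysis
#'
#' Names the predictor and outcome variable stems, the two distinguishable
#' role labels, and the chi-square multiplier convention. Columns are
#' resolved as `<stem>_<role>`; the first role is conventionally "male"
#' (paths `a_m`, `p_mf`) and the second "female" (`a_f`, `p_fm`).
#'
#' @param x_var Predictor stem (default `"depression"`).
#' @param y_var Outcome stem (default `"qol"`); must differ from `x_var`.
#' @param roles Two distinct role labels.
#' @param multiplier `"n_minus_1"` (Wishart likelihood, default) or `"n"`:
#'   the factor by which the ML discrepancy is scaled into the model
#'   chi-square. Material only in the third decimal of fit statistics.
#' @return An object of class `apim_spec`.
#' @export
apim_spec <- function(x_var = "depression", y_var = "qol",
                      roles = c("male", "female"),
                      multiplier = c("n_minus_1", "n")) {
  multiplier <- match.arg(multiplier)
  if (length(roles) != 2L || anyDuplicated(roles)) {
    stop_dyadkit("roles", "Exactly two distinguishable role labels are required.")
  }
  if (identical(x_var, y_var)) {
    stop_dyadkit("invalid_argument", "`x_var` and `y_var` must be distinct.")
  }
  structure(list(x_var = x_var, y_var = y_var, roles = roles,
                 multiplier = multiplier),
            class = "apim_spec")
}

apim_variables <- function(spec) {
  c(paste(spec$x_var, spec$roles, sep = "_"),
    paste(spec$y_var, spec$roles, sep = "_"))
}

multiplier_value <- function(spec, n) {
  if (spec$multiplier == "n") n else n - 1
}

#' Model-implied covariance matrix of an APIM
#'
#' Given the structural parameters, returns the implied 4 x 4 covariance
#' over (X_m, X_f, Y_m, Y_f). With the slope matrix
#' `B = rbind(c(a_m, p_mf), c(p_fm, a_f))` mapping (X_m, X_f) onto
#' (Y_m, Y_f): the X block is `phi`, the cross block is `B phi`, and the
#' Y block is `B phi t(B) + psi`.
#'
#' @param params Named list with `a_m`, `a_f`, `p_mf`, `p_fm`, the 2 x 2
#'   exogenous covariance `phi` and the 2 x 2 residual covariance `psi`.
#' @return Symmetric 4 x 4 matrix ordered (X_m, X_f, Y_m, Y_f).
#' @export
model_implied_sigma <- function(params) {
  phi <- check_symmetric(params$phi, "phi")
  psi <- check_symmetric(params$psi, "psi")
  if (any(diag(phi) <= 0) || any(diag(psi) <= 0)) {
    stop_dyadkit("invalid_argument", "`phi` and `psi` need positive diagonals.")
  }
  b <- rbind(c(params$a_m, params$p_mf),
             c(params$p_fm, params$a_f))
  s_yx <- b %*% phi
  sigma <- rbind(cbind(phi, t(s_yx)),
                 cbind(s_yx, b %*% phi %*% t(b) + psi))
  (sigma + t(sigma)) / 2
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The ML fit function of covariance-structure analysis:
#' `F = log det(sigma) + tr(S sigma^-1) - log det(S) - p`. It is
#' nonnegative, and zero exactly when `sigma = S`.
#'
#' @param S Sample covariance matrix (symmetric positive definite).
#' @param sigma Model-implied covariance matrix of the same order.
#' @return A nonnegative number.
#' @export
f_ml <- function(S, sigma) {
  if (!all(dim(S) == dim(sigma))) {
    stop_dyadkit("invalid_argument", "`S` and `sigma` must have the same order.")
  }
  p <- nrow(S)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  chSig <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(chS) || is.null(chSig)) {
    stop_dyadkit("not_positive_definite", "Both matrices must be positive definite.")
  }
  ld_s <- 2 * sum(log(diag(chS)))
  ld_sig <- 2 * sum(log(diag(chSig)))
  ld_sig + sum(diag(S %*% chol2inv(chSig))) - ld_s - p
}

# --- parameter vector <-> params list -------------------------------------
# Free-parameter order used for information matrices and optimization:
# (a_m, p_mf, p_fm, a_f, phi11, phi21, phi22, psi11, psi21, psi22).

params_to_theta <- function(params) {
  c(params$a_m, params$p_mf, params$p_fm, params$a_f,
    params$phi[1, 1], params$phi[2, 1], params$phi[2, 2],
    params$psi[1, 1], params$psi[2, 1], params$psi[2, 2])
}

theta_to_params <- function(theta) {
  list(a_m = theta[1], p_mf = theta[2], p_fm = theta[3], a_f = theta[4],
       phi = matrix(c(theta[5], theta[6], theta[6], theta[7]), 2),
       psi = matrix(c(theta[8], theta[9], theta[9], theta[10]), 2))
}

# Standardized paths from structural parameters, using model-implied SDs.
standardized_paths <- function(params) {
  sigma <- model_implied_sigma(params)
  sds <- sqrt(diag(sigma))          # (x_m, x_f, y_m, y_f)
  c(actor_m    = params$a_m  * sds[1] / sds[3],
    partner_mf = params$p_mf * sds[2] / sds[3],
    partner_fm = params$p_fm * sds[1] / sds[4],
    actor_f    = params$a_f  * sds[2] / sds[4])
}

# Expected-information covariance matrix of theta-hat: the inverse Hessian
# of (multiplier / 2) * F_ML at the estimate, computed numerically.
apim_vcov_theta <- function(S, theta_hat, mult) {
  fun <- function(th) f_ml(S, model_implied_sigma(theta_to_params(th)))
  h <- pracma::hessian(fun, theta_hat)
  h <- (h + t(h)) / 2
  inv <- tryCatch(solve(h), error = function(e) NULL)
  if (is.null(inv)) {
    stop_dyadkit("singular_information", "Information matrix is singular.")
  }
  (2 / mult) * inv
}

build_paths_table <- function(params, vcov_theta, roles, std_only_se = TRUE) {
  est <- params_to_theta(params)[1:4]
  std <- standardized_paths(params)
  labels <- apim_path_labels(roles)
  out <- tibble(
    path = c("actor_m", "partner_mf", "partner_fm", "actor_f"),
    estimate = est,
    std_estimate = unname(std[c("actor_m", "partner_mf", "partner_fm", "actor_f")])
  )
  if (!is.null(vcov_theta)) {
    se <- sqrt(pmax(diag(vcov_theta)[1:4], 0))
    # Delta method for standardized paths: gradient of beta(theta) against
    # the full parameter covariance.
    std_fun <- function(th) standardized_paths(theta_to_params(th))
    jac <- pracma::jacobian(std_fun, params_to_theta(params))
    std_se <- sqrt(pmax(diag(jac %*% vcov_theta %*% t(jac)), 0))
    out$se <- se
    out$z <- ifelse(se > 0, out$estimate / se, NA_real_)
    out$p <- 2 * pnorm(-abs(out$z))
    out$std_se <- std_se
    out$std_z <- ifelse(std_se > 0, out$std_estimate / std_se, NA_real_)
    out$std_p <- 2 * pnorm(-abs(out$std_z))
  } else {
    out$se <- out$z <- out$p <- out$std_se <- out$std_z <- out$std_p <- NA_real_
  }
  dplyr::left_join(out, labels, by = "path") |>
    dplyr::relocate("label", .after = "path")
}

resolve_apim_input <- function(data, spec) {
  vars <- apim_variables(spec)
  if (inherits(data, "moment_summary")) {
    summ <- subset_moments(data, vars)
    list(S = covariance_from_summary(summ), means = summ$means, n = summ$n)
  } else {
    data <- validate_dyad_table(data, c(spec$x_var, spec$y_var), spec$roles)
    n_complete <- sum(stats::complete.cases(data[vars]))
    if (n_complete < 5) {
      stop_dyadkit("insufficient_data",
                   sprintf("Need at least 5 complete dyads; have %d.", n_complete))
    }
    summ <- moments_from_table(data, vars)
    list(S = covariance_from_summary(summ), means = summ$means, n = summ$n)
  }
}

#' Fit the unconstrained (saturated) APIM
#'
#' Estimates actor effects (`actor_m`, `actor_f`), partner effects
#' (`partner_mf`: role-2 predictor on role-1 outcome; `partner_fm`: role-1
#' predictor on role-2 outcome), the exogenous predictor covariance and the
#' residual covariance, by maximum-likelihood covariance-structure analysis.
#' The unconstrained model is saturated, so the ML estimates are closed
#' form — each outcome regressed on both predictors from the covariance
#' matrix — and the model chi-square is 0 on 0 df.
#'
#' Standard errors for unstandardized slopes come from the expected
#' information of the ML problem (with the spec's multiplier convention);
#' standardized slopes `beta = slope * sd(x) / sd(y)` (model-implied SDs)
#' get delta-method SEs. Both are reported side by side and must not be
#' conflated: published dyadic analyses differ in which they print.
#'
#' @param data A wide dyad table (data frame) or a [moment_summary()]
#'   containing the four `<stem>_<role>` variables.
#' @param spec An [apim_spec()].
#' @param se Compute standard errors and Wald tests (default `TRUE`; skip
#'   for speed in large simulation loops).
#' @return An object of class `apim_fit`; see [tidy.apim_fit()] and
#'   [glance.apim_fit()].
#' @examples
#' fit <- fit_apim(infertile_couples_moments("total"),
#'                 apim_spec(y_var = "fertiqol_total"))
#' tidy(fit)
#' @export
fit_apim <- function(data, spec = apim_spec(), se = TRUE) {
  input <- resolve_apim_input(data, spec)
  S <- input$S
  n <- input$n

  r_x <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (abs(r_x) >= 1 - 1e-10) {
    stop_dyadkit("collinear", "The two predictors are (numerically) collinear.")
  }
  sxx <- S[1:2, 1:2]
  syx <- S[3:4, 1:2]
  b <- syx %*% solve(sxx)
  psi <- S[3:4, 3:4] - b %*% sxx %*% t(b)
  psi <- (psi + t(psi)) / 2
  params <- list(a_m = b[1, 1], p_mf = b[1, 2], p_fm = b[2, 1], a_f = b[2, 2],
                 phi = sxx, psi = psi)

  sigma <- model_implied_sigma(params)
  fval <- f_ml(S, sigma)
  mult <- multiplier_value(spec, n)

  vcov_theta <- if (se) apim_vcov_theta(S, params_to_theta(params), mult) else NULL
  paths <- build_paths_table(params, vcov_theta, spec$roles)

  structure(
    list(spec = spec, params = params, paths = paths, S = S,
         sigma = sigma, means = input$means, n = n,
         f_ml = fval, chi_square = mult * fval, df = 0L,
         converged = TRUE, vcov_theta = vcov_theta, constraint = NULL),
    class = "apim_fit"
  )
}

#' Standardized solution of an APIM fit
#'
#' Standardized path coefficients `beta = slope * sd(predictor) /
#' sd(outcome)` with SDs taken from the model-implied covariance (equal to
#' the sample SDs in the saturated model). A warning is issued if any
#' |beta| exceeds 1, which can happen in constrained or ill-scaled models.
#'
#' @param fit An `apim_fit`.
#' @return A tibble with columns `path`, `std_estimate`, `std_se`.
#' @export
standardized_solution <- function(fit) {
  stopifnot(inherits(fit, "apim_fit"))
  if (any(diag(fit$sigma)[3:4] <= 0)) {
    stop_dyadkit("zero_variance", "Model-implied outcome variance is not positive.")
  }
  out <- fit$paths[, c("path", "std_estimate", "std_se")]
  if (any(abs(out$std_estimate) > 1)) {
    warn("Standardized coefficient with |beta| > 1.")
  }
  out
}

#' Wald tests for APIM paths
#'
#' @param fit An `apim_fit` fitted with `se = TRUE`.
#' @return A tibble with `path`, `estimate`, `se`, `z`, `p` (unstandardized
#'   scale) and their `std_*` counterparts.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "apim_fit"))
  if (all(is.na(fit$paths$se))) {
    stop_dyadkit("invalid_argument", "Fit was computed with se = FALSE; refit with se = TRUE.")
  }
  fit$paths[, c("path", "estimate", "se", "z", "p",
                "std_estimate", "std_se", "std_z", "std_p")]
}

#' @rdname fit_apim
#' @param x,object An `apim_fit`.
#' @param ... Unused.
#' @export
tidy.apim_fit <- function(x, ...) {
  x$paths
}

#' @rdname fit_apim
#' @export
glance.apim_fit <- function(x, ...) {
  tibble(n = x$n, chi_square = x$chi_square, df = x$df,
         p_value = if (x$df > 0) pchisq(x$chi_square, x$df, lower.tail = FALSE) else NA_real_,
         f_ml = x$f_ml, converged = x$converged,
         constraint = if (is.null(x$constraint)) NA_character_ else x$constraint$kind)
}

#' @export
print.apim_fit <- function(x, digits = 3, ...) {
  kind <- if (is.null(x$constraint)) "saturated" else
    sprintf("constrained (%s, %s)", x$constraint$kind, x$constraint$scale)
  cat(sprintf("<apim_fit: %s, n = %d dyads, chi-square = %.4g on %d df>\n",
              kind, x$n, x$chi_square, x$df))
  print(as.data.frame(x$paths[, c("path", "estimate", "se", "std_estimate", "std_se", "p")]),
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_apim
#' @export
autoplot.apim_fit <- function(object, ...) {
  d <- object$paths
  d$lo <- d$std_estimate - qnorm(0.975) * d$std_se
  d$hi <- d$std_estimate + qnorm(0.975) * d$std_se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$std_estimate,
                                  y = stats::reorder(.data$path, .data$std_estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = "standardized coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
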