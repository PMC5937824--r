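# Equality-constrained APIM fits. A single equality constraint removes one
# free parameter (df = 1); the constrained model is no longer saturated, so
# its parameters are found by numerical minimization of the ML discrepancy
# over a reparameterized free vector in which the constrained pair shares
# one parameter. phi and psi are optimized on the log-Cholesky scale so
# every iterate is a proper covariance matrix.

#' Specify an equality constraint on APIM paths
#'
#' Three constraint kinds, each consuming one degree of freedom:
#' * `actor_equal` — equal actor effects across roles (`a_m = a_f`),
#' * `partner_equal` — equal partner effects (`p_mf = p_fm`),
#' * `actor_eq_partner` — within one role's outcome equation, actor effect
#'   equals partner effect (`role = "m"`: `a_m = p_mf`; `role = "f"`:
#'   `a_f = p_fm`).
#'
#' `scale` says on which scale the equality holds: raw slopes
#' (`"unstandardized"`, the default and common SEM practice) or
#' standardized coefficients (`"standardized"`, where the constrained
#' slopes differ by SD ratios). The two differ whenever predictor or
#' outcome SDs differ across roles.
#'
#' @param kind One of `"actor_equal"`, `"partner_equal"`,
#'   `"actor_eq_partner"`.
#' @param role For `actor_eq_partner`: `"m"` (first role's outcome) or
#'   `"f"` (second role's outcome).
#' @param scale `"unstandardized"` (default) or `"standardized"`.
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(kind = c("actor_equal", "partner_equal", "actor_eq_partner"),
                            role = NULL,
                            scale = c("unstandardized", "standardized")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (kind == "actor_eq_partner") {
    if (is.null(role)) {
      stop_dyadkit("invalid_argument", "`actor_eq_partner` needs role = \"m\" or \"f\".")
    }
    role <- match.arg(role, c("m", "f"))
  } else if (!is.null(role)) {
    stop_dyadkit("invalid_argument", "`role` applies only to actor_eq_partner.")
  }
  structure(list(kind = kind, role = role, scale = scale), class = "constraint_spec")
}

# log-Cholesky parameterization of a 2x2 SPD matrix:
# theta = (log l11, l21, log l22) for the lower factor L, M = L L'.
chol2_to_par <- function(m) {
  ch <- t(chol(m))
  c(log(ch[1, 1]), ch[2, 1], log(ch[2, 2]))
}

par_to_chol2 <- function(p) {
  l <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2)
  l %*% t(l)
}

# Positive root of (A) s^2 - (B) s - C = 0 for the model-implied outcome SD
# when a slope is pinned to a standardized value t (|t| < 1 guarantees
# A > 0 for the dominant term).
solve_sigma_y <- function(A, B, C) {
  disc <- B^2 + 4 * A * C
  if (A <= 0 || disc < 0) return(NA_real_)
  (B + sqrt(disc)) / (2 * A)
}

# Map a free-parameter vector to full APIM parameters under a constraint.
# Free-vector layouts (all length 9):
#   unstandardized: (shared, free_slope_1, free_slope_2, phi(3), psi(3))
#   standardized:   (z, free_slope_1, free_slope_2, phi(3), psi(3)) where
#                   the shared standardized value is tanh(z).
constrained_params <- function(free, constraint) {
  phi <- par_to_chol2(free[4:6])
  psi <- par_to_chol2(free[7:9])
  k <- constraint$kind
  sc <- constraint$scale
  if (sc == "unstandardized") {
    s <- free[1]
    slopes <- switch(k,
      actor_equal   = list(a_m = s, a_f = s, p_mf = free[2], p_fm = free[3]),
      partner_equal = list(a_m = free[2], a_f = free[3], p_mf = s, p_fm = s),
      actor_eq_partner = if (constraint$role == "m") {
        list(a_m = s, p_mf = s, a_f = free[2], p_fm = free[3])
      } else {
        list(a_f = s, p_fm = s, a_m = free[2], p_mf = free[3])
      })
    return(c(slopes, list(phi = phi, psi = psi)))
  }

  # standardized scale: shared value t = tanh(z) in (-1, 1), except for
  # actor_eq_partner, where both paths share the outcome SD and the
  # standardized equality reduces to the linear relation a * sx_own =
  # p * sx_other — then free[1] is the driving slope itself.
  t_std <- tanh(free[1])
  sx <- sqrt(diag(phi))
  if (k == "actor_eq_partner") {
    if (constraint$role == "m") {
      a_m <- free[1]; p_mf <- free[1] * sx[1] / sx[2]
      a_f <- free[2]; p_fm <- free[3]
      return(list(a_m = a_m, p_mf = p_mf, a_f = a_f, p_fm = p_fm,
                  phi = phi, psi = psi))
    } else {
      a_f <- free[1]; p_fm <- free[1] * sx[2] / sx[1]
      a_m <- free[2]; p_mf <- free[3]
      return(list(a_m = a_m, p_mf = p_mf, a_f = a_f, p_fm = p_fm,
                  phi = phi, psi = psi))
    }
  }

  if (k == "actor_equal") {
    p_mf <- free[2]; p_fm <- free[3]
    # male equation: sd_ym solves (1 - t^2) s^2 - (2 t p_mf phi12 / sx1) s
    #                              - (p_mf^2 phi22 + psi11) = 0, a_m = t s / sx1
    s_m <- solve_sigma_y(1 - t_std^2, 2 * t_std * p_mf * phi[1, 2] / sx[1],
                         p_mf^2 * phi[2, 2] + psi[1, 1])
    s_f <- solve_sigma_y(1 - t_std^2, 2 * t_std * p_fm * phi[1, 2] / sx[2],
                         p_fm^2 * phi[1, 1] + psi[2, 2])
    a_m <- t_std * s_m / sx[1]
    a_f <- t_std * s_f / sx[2]
    return(list(a_m = a_m, p_mf = p_mf, a_f = a_f, p_fm = p_fm,
                phi = phi, psi = psi))
  }

  # partner_equal, standardized: shared t = p_mf sx2 / sd_ym = p_fm sx1 / sd_yf
  a_m <- free[2]; a_f <- free[3]
  s_m <- solve_sigma_y(1 - t_std^2, 2 * a_m * t_std * phi[1, 2] / sx[2],
                       a_m^2 * phi[1, 1] + psi[1, 1])
  s_f <- solve_sigma_y(1 - t_std^2, 2 * a_f * t_std * phi[1, 2] / sx[1],
                       a_f^2 * phi[2, 2] + psi[2, 2])
  p_mf <- t_std * s_m / sx[2]
  p_fm <- t_std * s_f / sx[1]
  list(a_m = a_m, p_mf = p_mf, a_f = a_f, p_fm = p_fm, phi = phi, psi = psi)
}

constrained_start <- function(unc, constraint) {
  p <- unc$params
  phi_par <- chol2_to_par(p$phi)
  psi_par <- chol2_to_par(p$psi)
  k <- constraint$kind
  if (constraint$scale == "unstandardized" || k == "actor_eq_partner") {
    start <- switch(k,
      actor_equal   = c((p$a_m + p$a_f) / 2, p$p_mf, p$p_fm),
      partner_equal = c((p$p_mf + p$p_fm) / 2, p$a_m, p$a_f),
      actor_eq_partner = if (constraint$role == "m") {
        c((p$a_m + p$p_mf * sqrt(p$phi[2, 2] / p$phi[1, 1])) / 2, p$a_f, p$p_fm)
      } else {
        c((p$a_f + p$p_fm * sqrt(p$phi[1, 1] / p$phi[2, 2])) / 2, p$a_m, p$p_mf)
      })
    return(c(start, phi_par, psi_par))
  }
  std <- standardized_paths(p)
  start <- switch(k,
    actor_equal   = c(atanh(max(min((std["actor_m"] + std["actor_f"]) / 2, 0.99), -0.99)),
                      p$p_mf, p$p_fm),
    partner_equal = c(atanh(max(min((std["partner_mf"] + std["partner_fm"]) / 2, 0.99), -0.99)),
                      p$a_m, p$a_f))
  c(unname(start), phi_par, psi_par)
}

#' Fit an equality-constrained APIM
#'
#' Minimizes the ML discrepancy [f_ml()] over the reparameterized free
#' vector in which the constrained pair of paths shares one parameter
#' (9 free parameters; the constrained model has 1 df). Optimization is
#' quasi-Newton (BFGS) with numerically evaluated gradients; if the first
#' start does not converge, up to three seeded jittered restarts are tried.
#' Convergence requires a relative discrepancy change below 1e-10 or a
#' gradient norm below 1e-8 within 500 iterations; the `converged` flag is
#' set from what was actually achieved.
#'
#' @inheritParams fit_apim
#' @param constraint A [constraint_spec()].
#' @param start_seed Seed for the jittered restarts.
#' @return An `apim_fit` with `df = 1`, carrying the constraint.
#' @export
fit_constrained <- function(data, spec = apim_spec(), constraint,
                            se = TRUE, start_seed = 1L) {
  stopifnot(inherits(constraint, "constraint_spec"))
  unc <- fit_apim(data, spec, se = FALSE)
  S <- unc$S
  n <- unc$n
  mult <- multiplier_value(spec, n)

  objective <- function(free) {
    pars <- constrained_params(free, constraint)
    if (any(!is.finite(unlist(pars[c("a_m", "a_f", "p_mf", "p_fm")])))) {
      return(1e10)
    }
    sig <- model_implied_sigma(pars)
    out <- tryCatch(f_ml(S, sig), error = function(e) 1e10)
    if (!is.finite(out)) 1e10 else out
  }

  run_start <- function(start) {
    opt <- optim(start, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    grad_norm <- sqrt(sum(pracma::grad(objective, opt$par)^2))
    conv <- opt$convergence == 0 || grad_norm < 1e-8
    list(opt = opt, grad_norm = grad_norm, converged = conv)
  }

  start0 <- constrained_start(unc, constraint)
  res <- run_start(start0)
  if (!res$converged) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(start_seed)
    for (i in 1:3) {
      cand <- run_start(start0 * (1 + rnorm(length(start0), sd = 0.05)) +
                          rnorm(length(start0), sd = 0.01))
      if (cand$opt$value < res$opt$value) res <- cand
      if (res$converged) break
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  if (!res$converged) {
    warn(sprintf("Constrained fit did not meet convergence criteria (final gradient norm %.3e).",
                 res$grad_norm))
  }

  params <- constrained_params(res$opt$par, constraint)
  sigma <- model_implied_sigma(params)
  fval <- f_ml(S, sigma)

  vcov_theta <- if (se) {
    tryCatch(apim_vcov_constrained(S, res$opt$par, constraint, mult),
             error = function(e) NULL)
  } else NULL
  paths <- build_paths_table(params, vcov_theta, spec$roles)

  structure(
    list(spec = spec, params = params, paths = paths, S = S, sigma = sigma,
         means = unc$means, n = n, f_ml = fval, chi_square = mult * fval,
         df = 1L, converged = res$converged, vcov_theta = vcov_theta,
         constraint = constraint, grad_norm = res$grad_norm),
    class = "apim_fit"
  )
}

# Delta-method covariance of the full theta vector for a constrained fit:
# vcov of the free vector from the Hessian of F, pushed through the
# free -> theta map.
apim_vcov_constrained <- function(S, free_hat, constraint, mult) {
  fun <- function(fr) f_ml(S, model_implied_sigma(constrained_params(fr, constraint)))
  h <- pracma::hessian(fun, free_hat)
  h <- (h + t(h)) / 2
  vcov_free <- (2 / mult) * solve(h)
  to_theta <- function(fr) params_to_theta(constrained_params(fr, constraint))
  jac <- pracma::jacobian(to_theta, free_hat)
  jac %*% vcov_free %*% t(jac)
}

#' Chi-square difference test between nested APIM fits
#'
#' Computes `chi_sq_diff = chi_square(constrained) -
#' chi_square(unconstrained)` and `df_diff = df(constrained) -
#' df(unconstrained)`, with the p-value from the chi-square distribution on
#' `df_diff` degrees of freedom. Differences in (-1e-6, 0) are numerical
#' noise and are clamped to 0; more negative differences indicate
#' non-nested or mismatched fits and raise an error.
#'
#' @param constrained,unconstrained `apim_fit`s of the same data with the
#'   same multiplier convention.
#' @return An object of class `apim_constraint_test`.
#' @export
chisq_difference <- function(constrained, unconstrained) {
  stopifnot(inherits(constrained, "apim_fit"), inherits(unconstrained, "apim_fit"))
  if (constrained$n != unconstrained$n ||
      !identical(constrained$spec$multiplier, unconstrained$spec$multiplier) ||
      max(abs(constrained$S - unconstrained$S)) > 1e-10) {
    stop_dyadkit("non_nested", "Fits must come from the same data and multiplier.")
  }
  d_chi <- constrained$chi_square - unconstrained$chi_square
  if (d_chi < -1e-6) {
    stop_dyadkit("non_nested",
                 sprintf("Constrained chi-square is smaller than unconstrained by %.3g; fits are not nested.",
                         -d_chi))
  }
  d_chi <- max(d_chi, 0)
  d_df <- constrained$df - unconstrained$df
  if (d_df < 1) {
    stop_dyadkit("non_nested", "Constrained model must have more df than unconstrained.")
  }
  structure(
    list(chi_sq_diff = d_chi, df_diff = d_df,
         p = pchisq(d_chi, df = d_df, lower.tail = FALSE),
         constrained_fit = constrained, unconstrained_fit = unconstrained),
    class = "apim_constraint_test"
  )
}

#' @export
print.apim_constraint_test <- function(x, ...) {
  k <- x$constrained_fit$constraint
  cat(sprintf("<apim_constraint_test: %s (%s)>\n", k$kind, k$scale))
  cat(sprintf("  chi-square diff = %.4f on %d df, p = %.4g\n",
              x$chi_sq_diff, x$df_diff, x$p))
  invisible(x)
}

#' @rdname chisq_difference
#' @param x An `apim_constraint_test`.
#' @param ... Unused.
#' @export
tidy.apim_constraint_test <- function(x, ...) {
  k <- x$constrained_fit$constraint
  tibble(constraint = k$kind,
         role = k$role %||% NA_character_,
         scale = k$scale,
         chi_sq_diff = x$chi_sq_diff,
         df_diff = x$df_diff,
         p = x$p,
         converged = x$constrained_fit$converged)
}

#' Run the four standard equality-constraint tests
#'
#' Fits and tests, in a fixed order: (1) equal actor effects, (2) equal
#' partner effects, (3) actor = partner within the first role's outcome
#' equation, (4) actor = partner within the second role's. Each is a 1-df
#' chi-square difference test against the saturated model.
#'
#' @inheritParams fit_apim
#' @param scale Constraint scale passed to every [constraint_spec()].
#' @param alpha Decision level for the `significant` column.
#' @return A tibble with one row per test: `constraint`, `role`, `scale`,
#'   `chi_sq_diff`, `df_diff`, `p`, `significant`, `converged`.
#' @export
run_all_equality_tests <- function(data, spec = apim_spec(),
                                   scale = c("unstandardized", "standardized"),
                                   alpha = 0.05) {
  scale <- match.arg(scale)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  unc <- fit_apim(data, spec, se = FALSE)
  specs <- list(
    constraint_spec("actor_equal", scale = scale),
    constraint_spec("partner_equal", scale = scale),
    constraint_spec("actor_eq_partner", role = "m", scale = scale),
    constraint_spec("actor_eq_partner", role = "f", scale = scale)
  )
  purrr::map_dfr(specs, function(cs) {
    con <- fit_constrained(data, spec, cs, se = FALSE)
    res <- tidy(chisq_difference(con, unc))
    res$significant <- res$p < alpha
    res
  })
}
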