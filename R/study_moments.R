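# Summary statistics from a cross-sectional study of 180 infertile couples
# (male-female dyads at a fertility clinic) in which both partners completed
# the PHQ-9 (depression, 0-27) and the core FertiQoL (quality of life, 0-100,
# total + Emotional / Mind-Body / Relational / Social subscales). Correlations
# were published to two decimals; that rounding is the resolution limit of
# every reanalysis built on these moments.

study_variable_order <- c(
  "depression_male", "fertiqol_total_male", "fertiqol_emotional_male",
  "fertiqol_mind_body_male", "fertiqol_relational_male", "fertiqol_social_male",
  "depression_female", "fertiqol_total_female", "fertiqol_emotional_female",
  "fertiqol_mind_body_female", "fertiqol_relational_female", "fertiqol_social_female"
)

study_means <- c(4.82, 72.89, 67.34, 74.07, 80.12, 70.05,
                 6.76, 67.36, 56.16, 67.31, 77.08, 68.89)

study_sds <- c(5.47, 15.94, 22.19, 20.00, 16.51, 17.10,
               5.78, 16.11, 22.33, 19.74, 17.33, 18.74)

# Lower triangle of the published 12 x 12 Pearson correlation matrix,
# row by row in `study_variable_order`.
study_correlation_lower <- list(
  c(-0.61),
  c(-0.53,  0.91),
  c(-0.59,  0.90,  0.82),
  c(-0.34,  0.69,  0.47,  0.46),
  c(-0.55,  0.83,  0.67,  0.67,  0.46),
  c( 0.18, -0.21, -0.17, -0.22, -0.15, -0.17),
  c(-0.23,  0.36,  0.36,  0.32,  0.23,  0.28, -0.61),
  c(-0.12,  0.25,  0.30,  0.23,  0.08,  0.19, -0.58,  0.89),
  c(-0.22,  0.34,  0.33,  0.34,  0.18,  0.27, -0.61,  0.88,  0.80),
  c(-0.22,  0.31,  0.27,  0.20,  0.39,  0.19, -0.25,  0.63,  0.36,  0.37),
  c(-0.21,  0.30,  0.30,  0.27,  0.15,  0.27, -0.54,  0.86,  0.70,  0.69, 0.44)
)

study_correlations <- local({
  p <- length(study_variable_order)
  r <- diag(p)
  for (i in 2:p) {
    r[i, 1:(i - 1)] <- study_correlation_lower[[i - 1]]
  }
  r[upper.tri(r)] <- t(r)[upper.tri(r)]
  dimnames(r) <- list(study_variable_order, study_variable_order)
  r
})

#' Published summary moments of the infertile-couples depression/QoL study
#'
#' Means, SDs and the Pearson correlation matrix for PHQ-9 depression and
#' core FertiQoL scores of 180 male-female dyads experiencing infertility,
#' as printed in the source study's descriptive tables. These are sufficient
#' statistics for every covariance-based analysis in the package, so the
#' study's dyadic models can be refitted without access to raw data.
#'
#' With `outcome = NULL` the full 12-variable summary is returned. Naming a
#' FertiQoL outcome returns the 4-variable summary over
#' (`depression_male`, `depression_female`, `<outcome>_male`,
#' `<outcome>_female`) — the inputs of one actor-partner model fit.
#'
#' Because the published correlations carry two decimals, the 12-variable
#' matrix can be marginally indefinite; the tolerance built into
#' [moment_summary()] absorbs that rounding.
#'
#' @param outcome `NULL` for all 12 variables, or one of `"total"`,
#'   `"emotional"`, `"mind_body"`, `"relational"`, `"social"`.
#' @return A [moment_summary()] with `n = 180`.
#' @examples
#' infertile_couples_moments("total")
#' @export
infertile_couples_moments <- function(outcome = NULL) {
  full <- moment_summary(study_variable_order, study_means, study_sds,
                         study_correlations, n = 180, tol = 1e-2)
  if (is.null(outcome)) {
    return(full)
  }
  outcome <- match.arg(outcome, c("total", "emotional", "mind_body", "relational", "social"))
  stem <- paste0("fertiqol_", outcome)
  subset_moments(full, c("depression_male", "depression_female",
                         paste0(stem, "_male"), paste0(stem, "_female")))
}
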