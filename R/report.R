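#' Format p-values in publication style
#'
#' Values below `threshold` render as `"<threshold"` (e.g. `"<0.001"`);
#' others are rounded to `digits` decimals. Raw p-values are never lost:
#' JSON exports keep the numeric value alongside.
#'
#' @param p Numeric vector of p-values.
#' @param digits Decimals for displayed values.
#' @param threshold Display floor.
#' @return Character vector.
#' @export
format_p <- function(p, digits = 3, threshold = 0.001) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < threshold,
                paste0("<", format(threshold, scientific = FALSE)),
                formatC(round(p, digits), format = "f", digits = digits)))
}

round_cols <- function(d, cols, digits) {
  for (cl in intersect(cols, names(d))) d[[cl]] <- round(d[[cl]], digits)
  d
}

#' Render result tables to disk
#'
#' Writes each tibble in `results` to `out_dir` as TSV, JSON or a markdown
#' table. Numeric display follows the conventions of the source field:
#' 3 decimals for coefficients and correlations, 2 for t and chi-square
#' statistics, and p-values shown as `"<0.001"` below threshold — while the
#' JSON files retain full-precision values so that re-parsing them
#' reproduces the in-memory results.
#'
#' @param results Named list of data frames.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(results, format = c("tsv", "json", "markdown"), out_dir = ".") {
  format <- match.arg(format)
  if (!is.list(results) || is.null(names(results)) || any(names(results) == "")) {
    stop_dyadkit("invalid_argument", "`results` must be a named list of data frames.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coef_cols <- c("estimate", "std_estimate", "se", "std_se", "r", "bias",
                 "mean_estimate", "empirical_sd", "mean_se", "coverage_95")
  stat_cols <- c("t", "z", "std_z", "chi_square", "chi_sq_diff")

  paths <- purrr::imap_chr(results, function(d, name) {
    d <- as_tibble(d)
    if (format == "json") {
      path <- file.path(out_dir, paste0(name, ".json"))
      jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
      return(path)
    }
    shown <- round_cols(d, coef_cols, 3)
    shown <- round_cols(shown, stat_cols, 2)
    for (cl in intersect(c("p", "std_p", "p_value"), names(shown))) {
      shown[[cl]] <- format_p(shown[[cl]])
    }
    if (format == "tsv") {
      path <- file.path(out_dir, paste0(name, ".tsv"))
      readr::write_tsv(shown, path, na = "")
      return(path)
    }
    path <- file.path(out_dir, paste0(name, ".md"))
    header <- paste0("| ", paste(names(shown), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(shown)), collapse = "|"), "|")
    body <- apply(shown, 1, function(row) {
      paste0("| ", paste(ifelse(is.na(row), "", as.character(row)), collapse = " | "), " |")
    })
    writeLines(c(header, sep, body), path)
    path
  })
  invisible(unname(paths))
}

#' Run the full dyadic analysis pipeline
#'
#' Reproduces the study's analysis sequence on any of three input modes and
#' writes every table as TSV and JSON alongside a run manifest:
#'
#' 1. paired role comparisons for the predictor and each outcome,
#' 2. the correlation report,
#' 3. one saturated APIM per outcome (actor/partner effects, Wald tests),
#' 4. the four equality-constraint chi-square difference tests for the
#'    first outcome.
#'
#' Input modes: `data` may be a wide dyad table (`mode = "table"`), a
#' [moment_summary()] (`"summary"`; paired comparisons use the summary
#' moments and the correlation report the summary matrix), or a
#' [simulation_config()] (`"simulate"`; a table is drawn with `seed`).
#'
#' @param data Dyad table, moment summary, or simulation config.
#' @param x_var Predictor stem.
#' @param outcomes Character vector of outcome stems; the first one is used
#'   for the constraint tests.
#' @param roles Two role labels.
#' @param multiplier Chi-square multiplier convention, see [apim_spec()].
#' @param constraint_scale Scale for the equality constraints.
#' @param alpha Decision level for the constraint-test table.
#' @param out_dir Directory for the report bundle (`NULL`: nothing written).
#' @param seed Seed (used in simulate mode and recorded in the manifest).
#' @return Invisibly, a named list with elements `paired_comparisons`,
#'   `correlations`, `apim_paths`, `constraint_tests`, `fits`, `manifest`.
#' @export
run_study_pipeline <- function(data,
                               x_var = "depression",
                               outcomes = "qol",
                               roles = c("male", "female"),
                               multiplier = c("n_minus_1", "n"),
                               constraint_scale = c("unstandardized", "standardized"),
                               alpha = 0.05,
                               out_dir = NULL,
                               seed = 1L) {
  multiplier <- match.arg(multiplier)
  constraint_scale <- match.arg(constraint_scale)
  if (length(outcomes) < 1) {
    stop_dyadkit("invalid_argument", "Need at least one outcome stem.")
  }

  if (inherits(data, "simulation_config")) {
    mode <- "simulate"
    tab <- simulate_dyads(data, seed = seed)
    x_var <- data$x_var; outcomes <- data$y_var; roles <- data$roles
    summ <- NULL
  } else if (inherits(data, "moment_summary")) {
    mode <- "summary"
    summ <- data
    tab <- NULL
  } else {
    mode <- "table"
    tab <- validate_dyad_table(data, c(x_var, outcomes), roles)
    summ <- NULL
  }

  all_vars <- c(x_var, outcomes)
  # (1) paired comparisons, role 2 minus role 1
  paired <- if (mode == "summary") {
    purrr::map_dfr(all_vars, function(v) {
      va <- paste(v, roles[1], sep = "_"); vb <- paste(v, roles[2], sep = "_")
      sub <- subset_moments(summ, c(va, vb))
      res <- paired_t_from_summary(sub$means[[va]], sub$sds[[va]],
                                   sub$means[[vb]], sub$sds[[vb]],
                                   sub$correlations[va, vb], sub$n)
      dplyr::bind_cols(tibble(variable = v), res)
    })
  } else {
    paired_comparisons(tab, all_vars, roles)
  }

  # (2) correlations
  cors <- if (mode == "summary") {
    correlation_report_from_summary(summ)
  } else {
    correlation_report(tab, role_columns(all_vars, roles))
  }

  # (3) one APIM per outcome
  fits <- purrr::map(outcomes, function(y) {
    spec <- apim_spec(x_var = x_var, y_var = y, roles = roles, multiplier = multiplier)
    fit_apim(if (mode == "summary") summ else tab, spec)
  })
  names(fits) <- outcomes
  apim_paths <- purrr::imap_dfr(fits, function(f, y) {
    dplyr::bind_cols(tibble(outcome = y), tidy(f))
  })

  # (4) equality tests on the first outcome
  spec1 <- apim_spec(x_var = x_var, y_var = outcomes[1], roles = roles,
                     multiplier = multiplier)
  tests <- run_all_equality_tests(if (mode == "summary") summ else tab,
                                  spec1, scale = constraint_scale, alpha = alpha)

  results <- list(paired_comparisons = paired,
                  correlations = tidy(cors),
                  apim_paths = apim_paths,
                  constraint_tests = tests)
  manifest <- list(
    mode = mode,
    x_var = x_var, outcomes = outcomes, roles = roles,
    multiplier = multiplier, constraint_scale = constraint_scale,
    alpha = alpha, seed = seed,
    n = if (mode == "summary") summ$n else nrow(tab),
    config_hash = rlang::hash(list(mode, x_var, outcomes, roles, multiplier,
                                   constraint_scale, alpha, seed)),
    package_version = as.character(utils::packageVersion("dyadkit")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  if (!is.null(out_dir)) {
    render_tables(results, "tsv", out_dir)
    render_tables(results, "json", out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(results, list(fits = fits, manifest = manifest)))
}
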