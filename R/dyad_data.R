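# Dyad tables are ordinary tibbles in wide, one-row-per-dyad layout:
# a `dyad_id` column plus role-suffixed numeric columns `<var>_<role>`
# (e.g. depression_male, depression_female). The dyad -- not the
# individual -- is the sampling unit, so all fitting happens on these rows.

role_columns <- function(variables, roles) {
  as.vector(t(outer(variables, roles, paste, sep = "_")))
}

#' Validate a wide dyad table
#'
#' Checks the invariants of the one-row-per-dyad layout: a unique `dyad_id`,
#' two distinguishable role labels, and numeric role-suffixed columns for
#' every requested variable.
#'
#' @param data Data frame, one row per dyad.
#' @param variables Character vector of variable stems to require.
#' @param roles Two distinct role labels (default `c("male", "female")`).
#' @param id_col Name of the dyad identifier column.
#' @return The validated data as a tibble, invisibly usable in pipes.
#' @export
validate_dyad_table <- function(data, variables = character(),
                                roles = c("male", "female"),
                                id_col = "dyad_id") {
  if (length(roles) != 2L || anyDuplicated(roles)) {
    stop_dyadkit("roles", "Exactly two distinguishable role labels are required.")
  }
  data <- as_tibble(data)
  if (!id_col %in% names(data)) {
    stop_dyadkit("missing_column", sprintf("Missing dyad identifier column `%s`.", id_col))
  }
  if (anyDuplicated(data[[id_col]])) {
    dup <- unique(data[[id_col]][duplicated(data[[id_col]])])
    stop_dyadkit("duplicate_id",
                 sprintf("`%s` must be unique; duplicated: %s.",
                         id_col, paste(utils::head(dup, 5), collapse = ", ")))
  }
  needed <- role_columns(variables, roles)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_dyadkit("missing_column",
                 sprintf("Missing required column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  for (cl in needed) {
    if (!is.numeric(data[[cl]])) {
      stop_dyadkit("parse", sprintf("Column `%s` must be numeric.", cl))
    }
  }
  data
}

#' Read a wide dyad table from CSV
#'
#' Reads an RFC 4180 CSV with a header row, one row per dyad and
#' role-suffixed columns, and validates it with [validate_dyad_table()].
#' Cells that cannot be parsed as numbers are reported with their row
#' numbers rather than silently becoming `NA`; empty cells stay `NA`
#' (explicit missingness).
#'
#' @inheritParams validate_dyad_table
#' @param path CSV file path.
#' @param role_labels Two distinguishable role labels.
#' @param ... Passed on to [readr::read_csv()] (e.g. `na`, `locale`).
#' @return A tibble, one row per dyad.
#' @export
read_dyad_table <- function(path, variables = character(),
                            role_labels = c("male", "female"),
                            id_col = "dyad_id", ...) {
  if (!file.exists(path)) {
    stop_dyadkit("io", sprintf("File not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, ...)
  out <- raw
  for (cl in setdiff(names(raw), id_col)) {
    txt <- raw[[cl]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & is.na(num))
    if (length(bad) > 0) {
      stop_dyadkit("parse",
                   sprintf("Column `%s` has non-numeric cell(s) in data row(s) %s.",
                           cl, paste(utils::head(bad, 5), collapse = ", ")))
    }
    out[[cl]] <- num
  }
  validate_dyad_table(out, variables = variables, roles = role_labels, id_col = id_col)
}

#' Pivot a long (one row per individual) table to wide dyad layout
#'
#' Convenience bridge for data stored with one row per dyad member. The
#' wide, one-row-per-dyad layout is the canonical fitting input; this
#' helper only converts towards it.
#'
#' @param data Data frame with one row per individual.
#' @param role_col Column holding the role label of each row.
#' @param id_col Dyad identifier column.
#' @return A wide tibble with `<var>_<role>` columns.
#' @export
pivot_dyads_wider <- function(data, role_col = "role", id_col = "dyad_id") {
  data <- as_tibble(data)
  if (!all(c(role_col, id_col) %in% names(data))) {
    stop_dyadkit("missing_column",
                 sprintf("Columns `%s` and `%s` are required.", id_col, role_col))
  }
  tidyr::pivot_wider(data,
                     id_cols = dplyr::all_of(id_col),
                     names_from = dplyr::all_of(role_col),
                     values_from = -dplyr::all_of(c(id_col, role_col)),
                     names_glue = paste0("{.value}_{", role_col, "}"))
}

#' Construct and validate a moment summary
#'
#' A moment summary holds the sufficient statistics for all covariance-based
#' analyses in this package: variable names, means, sample SDs (denominator
#' n - 1), a Pearson correlation matrix, and the number of dyads. Published
#' tables of "mean +/- SD" plus a correlation matrix map directly onto it.
#'
#' Correlation matrices transcribed from print are rounded (typically to 2
#' decimals) and can be very slightly indefinite. Eigenvalues down to
#' `-tol` are accepted as rounding noise; beyond that the constructor
#' errors unless `repair = TRUE`, in which case negative eigenvalues are
#' clipped at zero and the matrix rescaled back to unit diagonal.
#'
#' @param variables Character vector of variable names.
#' @param means,sds Numeric vectors, one value per variable; `sds` > 0.
#' @param correlations Square correlation matrix (unit diagonal, symmetric).
#' @param n Number of dyads; must exceed the number of variables.
#' @param tol Eigenvalue tolerance for near-indefiniteness (default 1e-8).
#' @param repair Clip-and-rescale repair of an indefinite matrix
#'   (default `FALSE`: indefinite input is an error).
#' @return An object of class `moment_summary`.
#' @export
moment_summary <- function(variables, means, sds, correlations, n,
                           tol = 1e-8, repair = FALSE) {
  p <- length(variables)
  if (p < 1 || anyDuplicated(variables)) {
    stop_dyadkit("invalid_argument", "`variables` must be distinct names.")
  }
  if (length(means) != p || length(sds) != p) {
    stop_dyadkit("invalid_argument", "`means` and `sds` must match `variables` in length.")
  }
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds <= 0)) {
    stop_dyadkit("invalid_argument", "`sds` must be strictly positive and finite.")
  }
  correlations <- check_symmetric(as.matrix(correlations), "correlations")
  if (nrow(correlations) != p) {
    stop_dyadkit("invalid_argument", "`correlations` must be p x p.")
  }
  if (max(abs(diag(correlations) - 1)) > 1e-8 || max(abs(correlations)) > 1 + 1e-8) {
    stop_dyadkit("invalid_argument",
                 "`correlations` must have unit diagonal and entries in [-1, 1].")
  }
  check_count(n, "n", lower = 2)
  if (n < p + 1) {
    stop_dyadkit("invalid_argument",
                 sprintf("n = %d is too small for %d variables (need n >= p + 1).", n, p))
  }
  ev <- eigen(correlations, symmetric = TRUE)
  if (min(ev$values) < -tol) {
    if (!repair) {
      stop_dyadkit("not_positive_definite",
                   sprintf("Correlation matrix is indefinite (smallest eigenvalue %.3e). Set repair = TRUE to clip and rescale.",
                           min(ev$values)))
    }
    lam <- pmax(ev$values, 0)
    r <- ev$vectors %*% diag(lam, p) %*% t(ev$vectors)
    d <- 1 / sqrt(diag(r))
    correlations <- diag(d, p) %*% r %*% diag(d, p)
    correlations <- (correlations + t(correlations)) / 2
  }
  dimnames(correlations) <- list(variables, variables)
  structure(
    list(variables = variables,
         means = setNames(as.numeric(means), variables),
         sds = setNames(as.numeric(sds), variables),
         correlations = correlations,
         n = as.integer(n)),
    class = "moment_summary"
  )
}

#' @export
print.moment_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<moment_summary: %d variables, n = %d dyads>\n", length(x$variables), x$n))
  print(tibble(variable = x$variables, mean = x$means, sd = x$sds), n = Inf)
  cat("Correlations:\n")
  print(round(x$correlations, digits))
  invisible(x)
}

#' Compute sample moments from a dyad table
#'
#' Means, sample SDs (denominator n - 1) and the Pearson correlation matrix
#' of the selected columns after listwise deletion.
#'
#' @param data Data frame (typically a wide dyad table).
#' @param variables Columns to summarise (full column names).
#' @return A [moment_summary()] with `n` = number of complete rows.
#' @export
moments_from_table <- function(data, variables) {
  data <- as_tibble(data)
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols) > 0) {
    stop_dyadkit("missing_column",
                 sprintf("Missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[variables])
  storage.mode(m) <- "double"
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) {
    stop_dyadkit("insufficient_data",
                 sprintf("Need at least 2 complete rows; have %d after listwise deletion.", n))
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop_dyadkit("zero_variance",
                 sprintf("Zero-variance variable(s): %s.",
                         paste(variables[sds == 0], collapse = ", ")))
  }
  moment_summary(variables = variables,
                 means = colMeans(m),
                 sds = sds,
                 correlations = cor(m),
                 n = n)
}

#' Covariance matrix implied by a moment summary
#'
#' Returns `S = D R D` with `D = diag(sds)`: the covariance matrix whose
#' diagonal is `sds^2` and whose correlations are `R`.
#'
#' @param summary A [moment_summary()].
#' @return Symmetric covariance matrix with the summary's variable names.
#' @export
covariance_from_summary <- function(summary) {
  stopifnot(inherits(summary, "moment_summary"))
  d <- diag(summary$sds, length(summary$sds))
  s <- d %*% summary$correlations %*% d
  s <- (s + t(s)) / 2
  dimnames(s) <- dimnames(summary$correlations)
  s
}

#' Subset a moment summary
#'
#' @param summary A [moment_summary()].
#' @param variables Variables to keep, in the requested order.
#' @return A [moment_summary()] over the selected variables.
#' @export
subset_moments <- function(summary, variables) {
  stopifnot(inherits(summary, "moment_summary"))
  missing_vars <- setdiff(variables, summary$variables)
  if (length(missing_vars) > 0) {
    stop_dyadkit("missing_column",
                 sprintf("Summary lacks variable(s): %s.", paste(missing_vars, collapse = ", ")))
  }
  moment_summary(variables = variables,
                 means = summary$means[variables],
                 sds = summary$sds[variables],
                 correlations = summary$correlations[variables, variables],
                 n = summary$n)
}

#' Read a moment summary from JSON
#'
#' Accepts a JSON document with keys `variables`, `means`, `sds`,
#' `correlations` (array of arrays) and `n`.
#'
#' @param path JSON file path.
#' @inheritParams moment_summary
#' @return A [moment_summary()].
#' @export
read_moment_summary <- function(path, tol = 1e-8, repair = FALSE) {
  if (!file.exists(path)) {
    stop_dyadkit("io", sprintf("File not found: %s", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("variables", "means", "sds", "correlations", "n")
  missing_keys <- setdiff(needed, names(doc))
  if (length(missing_keys) > 0) {
    stop_dyadkit("parse",
                 sprintf("Summary JSON lacks key(s): %s.", paste(missing_keys, collapse = ", ")))
  }
  moment_summary(doc$variables, doc$means, doc$sds, as.matrix(doc$correlations),
                 doc$n, tol = tol, repair = repair)
}

#' Write a moment summary to JSON
#'
#' @param summary A [moment_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_moment_summary <- function(summary, path) {
  stopifnot(inherits(summary, "moment_summary"))
  jsonlite::write_json(
    list(variables = summary$variables,
         means = unname(summary$means),
         sds = unname(summary$sds),
         correlations = unname(summary$correlations),
         n = summary$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
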