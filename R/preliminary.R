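#' Paired t test from summary statistics
#'
#' Reconstructs the paired (correlated-samples) t test from the two group
#' means, SDs, their within-pair correlation and the number of pairs — the
#' quantities a descriptive table prints. The SD of the pairwise difference
#' is `sqrt(sd_a^2 + sd_b^2 - 2 r sd_a sd_b)`, and
#' `t = (mean_b - mean_a) / (sd_diff / sqrt(n))` on `n - 1` degrees of
#' freedom, two-sided.
#'
#' When every pair has an identical difference (`sd_diff = 0`) with a
#' nonzero mean difference the statistic is infinite; the result flags this
#' with `infinite_t = TRUE` rather than erroring.
#'
#' @param mean_a,mean_b Group means (b - a is the tested difference).
#' @param sd_a,sd_b Group SDs (sample, denominator n - 1); must be > 0.
#' @param r_ab Pearson correlation between paired members, in [-1, 1].
#' @param n Number of pairs (>= 2).
#' @return A one-row tibble: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `r_ab`,
#'   `n`, `mean_diff`, `sd_diff`, `t`, `df`, `p`, `infinite_t`.
#' @examples
#' # female vs male depression in the infertility study:
#' paired_t_from_summary(4.82, 5.47, 6.76, 5.78, r_ab = 0.18, n = 180)
#' @export
paired_t_from_summary <- function(mean_a, sd_a, mean_b, sd_b, r_ab, n) {
  check_number(mean_a, "mean_a"); check_number(mean_b, "mean_b")
  check_number(sd_a, "sd_a", lower = 0); check_number(sd_b, "sd_b", lower = 0)
  if (sd_a <= 0 || sd_b <= 0) {
    stop_dyadkit("invalid_argument", "SDs must be strictly positive.")
  }
  check_number(r_ab, "r_ab", lower = -1, upper = 1)
  n <- check_count(n, "n", lower = 2)

  mean_diff <- mean_b - mean_a
  var_diff <- sd_a^2 + sd_b^2 - 2 * r_ab * sd_a * sd_b
  sd_diff <- sqrt(max(var_diff, 0))
  infinite_t <- sd_diff == 0 && mean_diff != 0
  if (sd_diff == 0) {
    t_stat <- if (mean_diff == 0) 0 else Inf * sign(mean_diff)
    p <- if (mean_diff == 0) 1 else 0
  } else {
    t_stat <- mean_diff / (sd_diff / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  tibble(mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
         r_ab = r_ab, n = n, mean_diff = mean_diff, sd_diff = sd_diff,
         t = t_stat, df = n - 1L, p = p, infinite_t = infinite_t)
}

#' Paired t test from raw paired vectors
#'
#' Listwise-deletes incomplete pairs and applies the summary-statistic
#' paired t test to the sample moments, so the two routes agree exactly on
#' the same data.
#'
#' @param values_a,values_b Numeric vectors of equal length.
#' @return A one-row tibble as in [paired_t_from_summary()].
#' @export
paired_t_raw <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop_dyadkit("invalid_argument", "`values_a` and `values_b` must have equal length.")
  }
  keep <- stats::complete.cases(values_a, values_b)
  a <- as.numeric(values_a[keep]); b <- as.numeric(values_b[keep])
  if (length(a) < 2) {
    stop_dyadkit("insufficient_data", "Need at least 2 complete pairs.")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    # Degenerate columns have no defined Pearson correlation; handle the
    # difference directly (the statistic only depends on the differences).
    d <- b - a
    if (sd(d) == 0) {
      return(tibble(mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
                    r_ab = NA_real_, n = length(a), mean_diff = mean(d), sd_diff = 0,
                    t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                    df = length(a) - 1L, p = if (mean(d) == 0) 1 else 0,
                    infinite_t = mean(d) != 0))
    }
    t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
    return(tibble(mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
                  r_ab = NA_real_, n = length(a), mean_diff = mean(d), sd_diff = sd(d),
                  t = t_stat, df = length(a) - 1L,
                  p = 2 * pt(-abs(t_stat), df = length(a) - 1), infinite_t = FALSE))
  }
  paired_t_from_summary(mean(a), sd(a), mean(b), sd(b), cor(a, b), length(a))
}

#' Paired role comparisons for a dyad table
#'
#' The descriptive "male vs female" comparison table: one paired t test per
#' variable stem, contrasting `<var>_<roles[2]>` against `<var>_<roles[1]>`.
#'
#' @param data Wide dyad table.
#' @param variables Variable stems to compare.
#' @param roles Two role labels; the difference tested is role 2 minus role 1.
#' @return A tibble with one row per variable.
#' @export
paired_comparisons <- function(data, variables, roles = c("male", "female")) {
  data <- validate_dyad_table(data, variables, roles)
  purrr::map_dfr(variables, function(v) {
    res <- paired_t_raw(data[[paste(v, roles[1], sep = "_")]],
                        data[[paste(v, roles[2], sep = "_")]])
    dplyr::bind_cols(tibble(variable = v), res)
  })
}

#' McNemar test from discordant-pair counts
#'
#' Tests marginal homogeneity of a paired binary trait from the two
#' discordant cell counts. Without continuity correction
#' `chi^2 = (b - c)^2 / (b + c)`; with correction
#' `chi^2 = (|b - c| - 1)^2 / (b + c)` floored at 0. When `b + c = 0` the
#' statistic is 0 and p = 1 by convention. The default is no correction.
#'
#' @param discordant_b,discordant_c Counts of the two discordant cells.
#' @param continuity Apply the continuity correction (default `FALSE`).
#' @return A one-row tibble: `b`, `c`, `chi_square`, `df` (= 1), `p`.
#' @export
mcnemar_test <- function(discordant_b, discordant_c, continuity = FALSE) {
  b <- check_count(discordant_b, "discordant_b")
  cc <- check_count(discordant_c, "discordant_c")
  total <- b + cc
  if (total == 0) {
    chi2 <- 0
  } else if (continuity) {
    chi2 <- max(abs(b - cc) - 1, 0)^2 / total
  } else {
    chi2 <- (b - cc)^2 / total
  }
  p <- if (total == 0) 1 else pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(b = b, c = cc, chi_square = chi2, df = 1L, p = p)
}

star_label <- function(p, levels = c(`*` = 0.05, `**` = 0.01, `***` = 0.001)) {
  levels <- sort(levels, decreasing = TRUE)
  vapply(p, function(pi) {
    hit <- names(levels)[pi < levels]
    if (length(hit) == 0) "" else hit[length(hit)]
  }, character(1))
}

#' Pairwise correlation report with significance stars
#'
#' Pearson correlations over complete rows, with two-sided p-values from the
#' t transform `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom, and star annotations at configurable levels (defaults
#' 0.05 / 0.01 / 0.001).
#'
#' @param data Data frame.
#' @param variables Columns to correlate (>= 2).
#' @param star_levels Named numeric vector mapping star strings to p
#'   thresholds (stars assigned for p < threshold).
#' @return An object of class `correlation_report` with matrices `r`, `p`,
#'   `stars` and the sample size `n`. `tidy()` returns the long
#'   lower-triangle tibble; `autoplot()` draws a heat map.
#' @export
correlation_report <- function(data, variables,
                               star_levels = c(`*` = 0.05, `**` = 0.01, `***` = 0.001)) {
  if (length(variables) < 2) {
    stop_dyadkit("invalid_argument", "Need at least two variables.")
  }
  data <- as_tibble(data)
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols) > 0) {
    stop_dyadkit("missing_column",
                 sprintf("Missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[variables])
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) {
    stop_dyadkit("insufficient_data", "Need at least 3 complete rows.")
  }
  if (any(apply(m, 2, sd) == 0)) {
    stop_dyadkit("zero_variance", "Zero-variance column among `variables`.")
  }
  r <- cor(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix(star_label(p, star_levels), nrow(p), dimnames = dimnames(r))
  stars[is.na(p)] <- ""
  structure(list(r = r, p = p, stars = stars, n = n, star_levels = star_levels),
            class = "correlation_report")
}

#' Correlation report from a moment summary
#'
#' Same p-value transform and star annotation as [correlation_report()],
#' applied to an already-computed correlation matrix (e.g. a published one).
#'
#' @param summary A [moment_summary()].
#' @inheritParams correlation_report
#' @return A `correlation_report`.
#' @export
correlation_report_from_summary <- function(summary,
                                            star_levels = c(`*` = 0.05, `**` = 0.01, `***` = 0.001)) {
  stopifnot(inherits(summary, "moment_summary"))
  r <- summary$correlations
  n <- summary$n
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix(star_label(p, star_levels), nrow(p), dimnames = dimnames(r))
  stars[is.na(p)] <- ""
  structure(list(r = r, p = p, stars = stars, n = n, star_levels = star_levels),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_report: %d variables, n = %d>\n", nrow(x$r), x$n))
  shown <- matrix(paste0(format(round(x$r, digits)), x$stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  shown[upper.tri(shown, diag = FALSE)] <- ""
  print(shown, quote = FALSE)
  lv <- sort(x$star_levels, decreasing = TRUE)
  cat(paste(sprintf("%s p < %s", names(lv), lv), collapse = "; "), "\n")
  invisible(x)
}

#' @rdname correlation_report
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @export
tidy.correlation_report <- function(x, ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble(var1 = rownames(x$r)[idx[, 1]],
         var2 = colnames(x$r)[idx[, 2]],
         r = x$r[idx],
         p = x$p[idx],
         stars = x$stars[idx],
         n = x$n)
}

#' @rdname correlation_report
#' @param object A `correlation_report`.
#' @export
autoplot.correlation_report <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = paste0(sprintf("%.2f", .data$r), .data$stars)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a scale:
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total))` over
#' complete rows.
#'
#' @param items Data frame or matrix, respondents in rows, items in columns
#'   (>= 2 items, >= 2 complete respondents).
#' @return A single number (can be negative for badly behaved scales).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop_dyadkit("invalid_argument", "Need at least 2 items.")
  if (nrow(m) < 2) stop_dyadkit("insufficient_data", "Need at least 2 complete respondents.")
  total_var <- var(rowSums(m))
  if (total_var == 0) stop_dyadkit("zero_variance", "Total score has zero variance.")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}
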