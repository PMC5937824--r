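#' Default FertiQoL core item columns
#'
#' Column names for the 24 core FertiQoL items in their four 6-item
#' subscales: Emotional (`fq_emo_1..6`), Mind/Body (`fq_mb_1..6`),
#' Relational (`fq_rel_1..6`) and Social (`fq_soc_1..6`).
#'
#' @return Named list of four character vectors of length 6.
#' @export
fertiqol_core_items <- function() {
  list(
    emotional  = paste0("fq_emo_", 1:6),
    mind_body  = paste0("fq_mb_",  1:6),
    relational = paste0("fq_rel_", 1:6),
    social     = paste0("fq_soc_", 1:6)
  )
}

# Validate a numeric item matrix: integer values inside [lo, hi] or NA.
validate_items <- function(data, cols, lo, hi, instrument) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_dyadkit("item_count",
                 sprintf("%s scoring needs %d item columns; missing: %s.",
                         instrument, length(cols), paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[cols])
  if (!is.numeric(m)) {
    storage.mode(m) <- "double"
  }
  bad <- !is.na(m) & (m < lo | m > hi | m != round(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_dyadkit("item_range",
                 sprintf("%s item `%s` has out-of-range value %s in row %d (allowed integers %d-%d).",
                         instrument, cols[idx[2]], m[bad][1], idx[1], lo, hi))
  }
  m
}

#' Score the PHQ-9 depression questionnaire
#'
#' Sums the nine 0-3 item responses to a 0-27 total (higher = more
#' depressive symptoms). With `max_missing > 0`, totals for respondents with
#' up to that many missing items are prorated: `sum * 9 / n_answered`.
#'
#' @param data Data frame with one row per respondent containing the item
#'   columns. Missing responses are `NA`.
#' @param items Character vector of the nine item columns, in order.
#' @param max_missing Maximum number of missing items tolerated per
#'   respondent (default 0, i.e. complete responses only).
#' @return The input as a tibble with columns `phq9_total` and
#'   `phq9_n_missing` appended.
#' @examples
#' df <- tibble::tibble(!!!stats::setNames(as.list(c(1, 0, 2, 0, 1, 0, 0, 3, 2)),
#'                                         paste0("phq9_", 1:9)))
#' score_phq9(df)$phq9_total  # 9
#' @export
score_phq9 <- function(data, items = paste0("phq9_", 1:9), max_missing = 0) {
  if (length(items) != 9L) {
    stop_dyadkit("item_count", "PHQ-9 has exactly 9 items.")
  }
  check_count(max_missing, "max_missing")
  m <- validate_items(data, items, 0, 3, "PHQ-9")
  n_missing <- rowSums(is.na(m))
  if (any(n_missing > max_missing)) {
    stop_dyadkit("missing_items",
                 sprintf("%d respondent(s) exceed max_missing = %d missing PHQ-9 items.",
                         sum(n_missing > max_missing), max_missing))
  }
  answered <- 9 - n_missing
  total <- rowSums(m, na.rm = TRUE) * 9 / answered
  dplyr::mutate(as_tibble(data),
                phq9_total = total,
                phq9_n_missing = as.integer(n_missing))
}

#' Score the core FertiQoL questionnaire
#'
#' Scores the 24-item core module: four 6-item subscales (Emotional,
#' Mind/Body, Relational, Social) and a total, each rescaled to 0-100
#' (higher = better quality of life). A subscale score is
#' `mean(answered items) * 25`; the total is `mean(all answered core items)
#' * 25` (an answered-item-weighted mean, not the mean of subscale scores).
#'
#' Items are consumed pre-oriented so that 4 is the best quality-of-life
#' response. If your data still carry the instrument's original keying,
#' pass the reverse-keyed column names via `reverse_keyed`; those items are
#' recoded as `4 - value` before scoring.
#'
#' @param data Data frame with one row per respondent.
#' @param items Named list of four character vectors (6 columns each), as
#'   returned by [fertiqol_core_items()].
#' @param min_answered Minimum answered items per subscale (default 3 of 6).
#' @param reverse_keyed Optional character vector of item columns to recode
#'   as `4 - value` before scoring.
#' @return The input as a tibble with `fertiqol_emotional`,
#'   `fertiqol_mind_body`, `fertiqol_relational`, `fertiqol_social`,
#'   `fertiqol_total` and `fertiqol_n_missing` appended.
#' @examples
#' resp <- tibble::as_tibble(stats::setNames(as.list(rep(2, 24)),
#'                                           unlist(fertiqol_core_items())))
#' score_fertiqol_core(resp)$fertiqol_total  # 50
#' @export
score_fertiqol_core <- function(data,
                                items = fertiqol_core_items(),
                                min_answered = 3,
                                reverse_keyed = NULL) {
  cols <- unlist(items, use.names = FALSE)
  if (length(items) != 4L || length(cols) != 24L ||
      !setequal(names(items), c("emotional", "mind_body", "relational", "social"))) {
    stop_dyadkit("item_count",
                 "Core FertiQoL has 4 named subscales (emotional, mind_body, relational, social) of 6 items each.")
  }
  check_count(min_answered, "min_answered", lower = 1)
  m <- validate_items(data, cols, 0, 4, "FertiQoL")
  if (!is.null(reverse_keyed)) {
    unknown <- setdiff(reverse_keyed, cols)
    if (length(unknown) > 0) {
      stop_dyadkit("invalid_argument",
                   sprintf("reverse_keyed names not among item columns: %s",
                           paste(unknown, collapse = ", ")))
    }
    m[, reverse_keyed] <- 4 - m[, reverse_keyed]
  }

  subscale_score <- function(sub_cols) {
    sm <- m[, sub_cols, drop = FALSE]
    answered <- rowSums(!is.na(sm))
    if (any(answered < min_answered)) {
      stop_dyadkit("missing_items",
                   sprintf("%d respondent(s) answered fewer than %d of %d items in a subscale.",
                           sum(answered < min_answered), min_answered, length(sub_cols)))
    }
    rowMeans(sm, na.rm = TRUE) * 25
  }

  scores <- purrr::map(items, subscale_score)
  total <- rowMeans(m, na.rm = TRUE) * 25
  dplyr::mutate(as_tibble(data),
                fertiqol_emotional  = scores$emotional,
                fertiqol_mind_body  = scores$mind_body,
                fertiqol_relational = scores$relational,
                fertiqol_social     = scores$social,
                fertiqol_total      = total,
                fertiqol_n_missing  = as.integer(rowSums(is.na(m))))
}
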