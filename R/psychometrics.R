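#' Raw-score scoring and internal consistency
#'
#' Scale scores are raw sums over a subscale's items, computed per informant
#' and averaged over the informants available for each child (the published
#' scoring rule). Reliability is Cronbach's alpha on informant-averaged item
#' scores, with the conventional interpretation bands at
#' 0.50/0.60/0.70/0.80/0.90.
#'
#' @name psychometrics
NULL

#' Score a subscale for every child
#'
#' Within an informant's sum a missing item counts 0 (no proration); an
#' informant missing more than `max_missing_frac` of the subscale's items is
#' dropped for this scale. The child score is the mean over the informants
#' retained. Children ending up with zero informants are excluded with a
#' warning.
#'
#' @param cohort A `cohort` object.
#' @param subscale A [subscale_definition()].
#' @param case_groups Character vector of group labels counting as cases
#'   (default "ASD").
#' @param age_split First age (years) of the adolescent band (default 12:
#'   child = 6-11, adolescent = 12-18).
#' @param max_missing_frac Per-informant missing-item tolerance (default 0.1).
#' @return A `scale_score_table` data.frame: `child_id`, `score`, `group`,
#'   `is_case`, `gender`, `age_band`, `n_informants`; attribute `k` holds the
#'   subscale size.
#' @export
score_scale <- function(cohort, subscale, case_groups = "ASD",
                        age_split = 12, max_missing_frac = 0.1) {
  stopifnot(inherits(subscale, "subscale_definition"))
  k <- length(subscale$item_ids)
  if (!k) stop("subscale is empty", call. = FALSE)
  rows <- cohort$responses[cohort$responses$item_id %in% subscale$item_ids, ,
                           drop = FALSE]
  key <- interaction(rows$child_id, rows$informant, drop = TRUE)
  sums <- tapply(rows$score, key, sum)
  n_items <- tapply(rows$score, key, length)
  keep <- n_items >= (1 - max_missing_frac) * k
  ids <- strsplit(names(sums), ".", fixed = TRUE)
  inf_tab <- data.frame(
    child_id = as.integer(vapply(ids, `[[`, character(1), 1L)),
    informant = vapply(ids, `[[`, character(1), 2L),
    sum = as.numeric(sums), stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  score <- tapply(inf_tab$sum, inf_tab$child_id, mean)
  n_inf <- tapply(inf_tab$sum, inf_tab$child_id, length)
  out <- data.frame(child_id = as.integer(names(score)),
                    score = as.numeric(score),
                    n_informants = as.integer(n_inf))
  dropped <- setdiff(cohort$children$child_id, out$child_id)
  if (length(dropped)) {
    warning(length(dropped), " child(ren) excluded: no informant passed the ",
            "missing-item cap", call. = FALSE)
  }
  ch <- cohort$children
  idx <- match(out$child_id, ch$child_id)
  out$group <- ch$group[idx]
  out$is_case <- out$group %in% case_groups
  out$gender <- ch$gender[idx]
  out$age_band <- ifelse(ch$age[idx] < age_split, "child", "adolescent")
  out <- out[, c("child_id", "score", "group", "is_case", "gender",
                 "age_band", "n_informants")]
  attr(out, "k") <- k
  attr(out, "subscale") <- subscale$name
  class(out) <- c("scale_score_table", "data.frame")
  out
}

#' Children-by-items matrix of informant-averaged item scores
#'
#' @param cohort A `cohort` object.
#' @param subscale A [subscale_definition()].
#' @return Numeric matrix (rows: children with complete averaged item scores,
#'   named by child_id; columns: item IDs).
#' @export
item_score_matrix <- function(cohort, subscale) {
  stopifnot(inherits(subscale, "subscale_definition"))
  rows <- cohort$responses[cohort$responses$item_id %in% subscale$item_ids, ,
                           drop = FALSE]
  avg <- tapply(rows$score, list(rows$child_id, rows$item_id), mean)
  mat <- avg[, as.character(subscale$item_ids), drop = FALSE]
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  storage.mode(mat) <- "double"
  mat
}

#' Cronbach's alpha with interpretation band
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of row sums)`, all
#' variances with denominator n-1. Bands follow the cited convention:
#' `[0.50,0.60)` poor, `[0.60,0.70)` questionable, `[0.70,0.80)` acceptable,
#' `[0.80,0.90)` good, `[0.90,1]` excellent; values below 0.50 are labelled
#' `unacceptable`.
#'
#' @param item_matrix Children x items matrix of (informant-averaged) scores.
#' @return A `reliability_result`: list with `alpha`, `band`, `k`, `n`.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix); n <- nrow(item_matrix)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  if (n < 3) stop("need at least 3 children", call. = FALSE)
  total_var <- stats::var(rowSums(item_matrix))
  if (!is.finite(total_var) || total_var <= 0) {
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  }
  item_vars <- apply(item_matrix, 2, stats::var)
  alpha <- k / (k - 1) * (1 - sum(item_vars) / total_var)
  structure(list(alpha = alpha, band = alpha_band(alpha), k = k, n = n),
            class = "reliability_result")
}

#' Interpretation band for a reliability coefficient
#'
#' @param alpha Numeric value(s) (alpha is bounded above by 1).
#' @return Character band label(s).
#' @export
alpha_band <- function(alpha) {
  cut_pts <- c(-Inf, 0.50, 0.60, 0.70, 0.80, 0.90, 1 + 1e-12)
  labs <- c("unacceptable", "poor", "questionable", "acceptable", "good",
            "excellent")
  labs[findInterval(alpha, cut_pts, rightmost.closed = TRUE)]
}

#' @export
#' @method print reliability_result
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%s; k = %d items, n = %d)\n",
              x$alpha, x$band, x$k, x$n))
  invisible(x)
}
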