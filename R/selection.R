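#' Item-selection rules for subscale construction
#'
#' Two complementary rules build the new screening subscales: the data-driven
#' rule keeps an item when the ASD group scored significantly higher than at
#' least `min_groups` of the `n_comparison_groups` comparison groups (the
#' published instantiation: 7 of 10, i.e. a 70% criterion at alpha < 0.001);
#' the clinician-expert rule keeps an item when at least `min_votes` of
#' `n_clinicians` raters flagged it as ASD-typical (11 of 15, 73.33%).
#'
#' @name selection
NULL

#' Selection configuration
#'
#' When `min_groups` is not given it is derived from `fraction` as
#' `ceiling(fraction * n_comparison_groups)`; an explicitly supplied integer
#' wins over the fraction.
#'
#' @param alpha Per-contrast significance level.
#' @param min_groups Minimum comparison groups the ASD group must exceed.
#' @param n_comparison_groups Number of comparison groups voting.
#' @param min_votes Minimum clinician votes for inclusion.
#' @param n_clinicians Panel size.
#' @param fraction Inclusion fraction used when `min_groups` is NULL.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.001, min_groups = NULL,
                             n_comparison_groups = 10, min_votes = 11,
                             n_clinicians = 15, fraction = 0.7) {
  if (is.null(min_groups)) min_groups <- ceiling(fraction * n_comparison_groups)
  stopifnot(alpha > 0, alpha < 1,
            min_groups > 0, min_groups <= n_comparison_groups,
            min_votes > 0, min_votes <= n_clinicians)
  structure(list(alpha = alpha, min_groups = as.integer(min_groups),
                 n_comparison_groups = as.integer(n_comparison_groups),
                 min_votes = as.integer(min_votes),
                 n_clinicians = as.integer(n_clinicians)),
            class = "selection_config")
}

#' Data-driven item selection from comparison verdicts
#'
#' @param verdicts List of [compare_to_groups()] results, one per candidate
#'   item. Items with failed fits (`converged = FALSE`) are excluded.
#' @param config A [selection_config()].
#' @return A [subscale_definition()] named "DataDriven".
#' @export
select_items_data_driven <- function(verdicts, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  keep <- vapply(verdicts, function(v) {
    stopifnot(inherits(v, "comparison_verdicts"))
    isTRUE(v$converged) && v$n_significant >= config$min_groups
  }, logical(1))
  ids <- vapply(verdicts, `[[`, integer(1), "item_id")
  subscale_definition("DataDriven", ids[keep])
}

#' Clinician-expert item selection from a ratings matrix
#'
#' @param ratings Binary matrix, clinicians x items, columns named by item ID;
#'   must be complete (no missing cells).
#' @param config A [selection_config()].
#' @return A [subscale_definition()] named "ClinicianExpert".
#' @export
select_items_clinician <- function(ratings, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"), is.matrix(ratings))
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  if (!all(ratings %in% c(0L, 1L))) {
    stop("ratings must be binary 0/1", call. = FALSE)
  }
  if (is.null(colnames(ratings))) {
    stop("ratings columns must be named by item ID", call. = FALSE)
  }
  votes <- colSums(ratings)
  subscale_definition("ClinicianExpert",
                      as.integer(colnames(ratings)[votes >= config$min_votes]))
}

#' Vote fraction implied by a selection configuration
#'
#' @param config A [selection_config()].
#' @return Percentage `100 * min_votes / n_clinicians`, rounded to two
#'   decimals (e.g. 73.33 for 11 of 15).
#' @export
vote_fraction <- function(config = selection_config()) {
  round(100 * config$min_votes / config$n_clinicians, 2)
}
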