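#' Per-item informant-nested mixed models
#'
#' One linear mixed model per inventory item: informant reports (level one)
#' nested in children (level two) via a child random intercept, with primary
#' classification as a categorical predictor (ASD as the reference level) and
#' mean-centered age plus gender (girl = 1) as covariates. Ordinal 0/1/2
#' scores are treated as numeric, matching the mean-comparison reading of the
#' selection rule. Estimation is REML; Wald tests use a Normal reference
#' (large-sample), so p-values are approximate for small cohorts.
#'
#' @name mixed_model
NULL

#' Fit the random-intercept model for one item
#'
#' Children with a single informant contribute their one row (no listwise
#' deletion). When the fit fails outright the result is flagged
#' `converged = FALSE` and carries empty estimates; selection treats such items
#' as not selectable.
#'
#' @param cohort A `cohort` object (or any list with `responses`/`children`).
#' @param item_id Item to fit.
#' @param reference_group Group used as the contrast reference (default "ASD").
#' @param reml Use REML (default) or ML.
#' @return An `item_model_fit`: list with `item_id`, `beta`, `se` (all fixed
#'   effects), `contrasts` (data.frame: `group`, `estimate`, `se`, `z`, `p` for
#'   each non-reference group; the estimate is group minus reference),
#'   `tau2`, `sigma2`, `n_children`, `n_rows`, `converged`, `messages`.
#' @export
fit_item_model <- function(cohort, item_id, reference_group = "ASD",
                           reml = TRUE) {
  rows <- cohort$responses[cohort$responses$item_id == item_id, , drop = FALSE]
  if (!nrow(rows)) stop("no responses for item ", item_id, call. = FALSE)
  dat <- merge(rows, cohort$children, by = "child_id")
  fit_item_model_data(dat, item_id, reference_group, reml)
}

# Core fitter on an already-merged per-item data.frame.
fit_item_model_data <- function(dat, item_id, reference_group = "ASD",
                                reml = TRUE) {
  if (!reference_group %in% dat$group) {
    stop("reference group '", reference_group, "' absent from data",
         call. = FALSE)
  }
  dat$group <- stats::relevel(factor(dat$group), ref = reference_group)
  dat$age_c <- dat$age - mean(dat$age)
  dat$girl <- as.integer(dat$gender == "girl")
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      suppressMessages(lme4::lmer(
        score ~ group + age_c + girl + (1 | child_id),
        data = dat, REML = reml,
        control = lme4::lmerControl(check.conv.singular = "ignore")
      )),
      error = function(e) e
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  empty <- function() structure(list(
    item_id = item_id, beta = numeric(0), se = numeric(0),
    contrasts = data.frame(group = character(0), estimate = numeric(0),
                           se = numeric(0), z = numeric(0), p = numeric(0)),
    tau2 = NA_real_, sigma2 = NA_real_,
    n_children = length(unique(dat$child_id)), n_rows = nrow(dat),
    converged = FALSE, messages = msgs
  ), class = "item_model_fit")
  if (inherits(fit, "error")) {
    msgs <- c(msgs, conditionMessage(fit))
    return(empty())
  }
  converged <- !any(grepl("failed to converge", msgs, fixed = TRUE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  tau2 <- as.numeric(vc$child_id[1, 1])
  sigma2 <- attr(vc, "sc")^2
  cn <- names(beta)
  is_grp <- startsWith(cn, "group")
  z <- beta[is_grp] / se[is_grp]
  contrasts <- data.frame(
    group = sub("^group", "", cn[is_grp]),
    estimate = unname(beta[is_grp]),
    se = unname(se[is_grp]),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  structure(list(
    item_id = item_id, beta = beta, se = se, contrasts = contrasts,
    tau2 = tau2, sigma2 = sigma2,
    n_children = length(unique(dat$child_id)), n_rows = nrow(dat),
    converged = converged, messages = msgs
  ), class = "item_model_fit")
}

#' @export
#' @method print item_model_fit
print.item_model_fit <- function(x, ...) {
  cat(sprintf("<item %d fit: %d children, %d rows, tau2=%.3f, sigma2=%.3f%s>\n",
              x$item_id, x$n_children, x$n_rows, x$tau2, x$sigma2,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Fit models for many items
#'
#' @param cohort A `cohort` object.
#' @param item_ids Items to fit (default: all items present).
#' @param ... Passed to the per-item fitter.
#' @return Named list of `item_model_fit` objects (names are item IDs).
#' @export
fit_all_items <- function(cohort, item_ids = NULL, ...) {
  if (is.null(item_ids)) item_ids <- sort(unique(cohort$responses$item_id))
  dat_all <- merge(cohort$responses, cohort$children, by = "child_id")
  split_dat <- split(dat_all, dat_all$item_id)
  fits <- lapply(item_ids, function(j) {
    fit_item_model_data(split_dat[[as.character(j)]], j, ...)
  })
  names(fits) <- item_ids
  fits
}

#' Flatten fits into a per-item table
#'
#' One row per item and comparison group, with variance components and
#' convergence flags; the selection audit-trail format.
#'
#' @param fits List of `item_model_fit` objects.
#' @return data.frame with columns `item_id`, `group`, `estimate`, `se`, `z`,
#'   `p`, `tau2`, `sigma2`, `n_children`, `n_rows`, `converged`.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    if (!nrow(f$contrasts)) {
      return(data.frame(item_id = f$item_id, group = NA_character_,
                        estimate = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, tau2 = f$tau2, sigma2 = f$sigma2,
                        n_children = f$n_children, n_rows = f$n_rows,
                        converged = f$converged, stringsAsFactors = FALSE))
    }
    cbind(data.frame(item_id = f$item_id, stringsAsFactors = FALSE),
          f$contrasts,
          data.frame(tau2 = f$tau2, sigma2 = f$sigma2,
                     n_children = f$n_children, n_rows = f$n_rows,
                     converged = f$converged))
  }))
}

#' ASD-versus-comparison-group verdicts for one item
#'
#' A comparison group g earns a TRUE flag when the two-sided Wald p-value of
#' its contrast is below `alpha` AND the contrast sign indicates the reference
#' (ASD) group scoring higher (group-minus-ASD estimate negative).
#' Inestimable contrasts are FALSE.
#'
#' @param fit An `item_model_fit`.
#' @param alpha Significance level (default 0.001).
#' @return A `comparison_verdicts`: list with `item_id`, `verdicts` (data.frame
#'   `group`, `asd_higher_significant`), `n_significant`, `converged`.
#' @export
compare_to_groups <- function(fit, alpha = 0.001) {
  stopifnot(inherits(fit, "item_model_fit"))
  if (!fit$converged || !nrow(fit$contrasts)) {
    v <- data.frame(group = fit$contrasts$group,
                    asd_higher_significant = logical(nrow(fit$contrasts)))
    return(structure(list(item_id = fit$item_id, verdicts = v,
                          n_significant = 0L, converged = FALSE),
                     class = "comparison_verdicts"))
  }
  ok <- is.finite(fit$contrasts$p) & is.finite(fit$contrasts$estimate)
  flag <- ok & fit$contrasts$p < alpha & fit$contrasts$estimate < 0
  v <- data.frame(group = fit$contrasts$group, asd_higher_significant = flag,
                  stringsAsFactors = FALSE)
  structure(list(item_id = fit$item_id, verdicts = v,
                 n_significant = sum(flag), converged = TRUE),
            class = "comparison_verdicts")
}
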