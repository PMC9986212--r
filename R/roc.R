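#' ROC machinery: AUC, curve comparisons, cut-offs
#'
#' AUC is the Mann-Whitney probability that a random case outscores a random
#' control, ties counting one half. Standard errors and the paired-curve test
#' use DeLong's structural components; independent-curve comparisons use the
#' Hanley-McNeil variance approximation. Cut-offs are chosen per
#' gender-by-age-band stratum: a lenient subclinical cut-off targeting high
#' sensitivity and a stricter clinical cut-off at the
#' sensitivity/specificity equilibrium (maximum Youden's J by default).
#' Classification is positive at score >= cutoff.
#'
#' @name roc
NULL

# DeLong structural components. psi(x,y) = 1, 1/2, 0 as x >, =, < y.
# v10: one entry per case (mean psi against all controls); v01: per control.
delong_components <- function(cases, controls) {
  cmp <- outer(cases, controls, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

split_scores <- function(scores) {
  stopifnot(inherits(scores, "data.frame"), all(c("score", "is_case") %in%
                                                  names(scores)))
  list(cases = scores$score[scores$is_case],
       controls = scores$score[!scores$is_case])
}

#' Interpretation band for an AUC
#'
#' @param auc Numeric AUC value(s).
#' @return "poor" below 0.70, "fair" `[0.70,0.80)`, "good" `[0.80,0.90)`,
#'   "excellent" `[0.90,1]`.
#' @export
auc_band <- function(auc) {
  labs <- c("poor", "fair", "good", "excellent")
  labs[findInterval(auc, c(-Inf, 0.70, 0.80, 0.90), rightmost.closed = FALSE)]
}

#' AUC with DeLong standard error and confidence interval
#'
#' @param scores A `scale_score_table` (or any data.frame with `score` and
#'   logical `is_case`), or a numeric vector of case scores when `controls`
#'   is given.
#' @param controls Optional numeric vector of control scores.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A `roc_result`: list with `auc`, `se`, `ci95` (length-2), `band`,
#'   `n_cases`, `n_controls`, and the structural components `v10`, `v01`.
#' @export
roc_auc <- function(scores, controls = NULL, conf_level = 0.95) {
  if (is.null(controls)) {
    sp <- split_scores(scores)
    cases <- sp$cases; controls <- sp$controls
  } else {
    cases <- as.numeric(scores)
  }
  m <- length(cases); n <- length(controls)
  if (m < 1 || n < 1) stop("need at least one case and one control", call. = FALSE)
  dc <- delong_components(cases, controls)
  var_auc <- if (m > 1 && n > 1) {
    stats::var(dc$v10) / m + stats::var(dc$v01) / n
  } else NA_real_
  se <- sqrt(var_auc)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.finite(se)) c(max(0, dc$auc - zq * se), min(1, dc$auc + zq * se))
        else c(NA_real_, NA_real_)
  structure(list(auc = dc$auc, se = se, ci95 = ci, band = auc_band(dc$auc),
                 n_cases = m, n_controls = n, v10 = dc$v10, v01 = dc$v01),
            class = "roc_result")
}

#' @export
#' @method print roc_result
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%s), SE = %.3f, 95%% CI %.3f-%.3f (%d cases, %d controls)\n",
              x$auc, x$band, x$se, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Both score sets must cover the same children with the same case/control
#' membership (the paired design: two subscales scored on one sample).
#'
#' @param scores_a,scores_b `scale_score_table`s over identical children, or
#'   numeric vectors when `is_case` is given.
#' @param is_case Optional logical vector when raw vectors are supplied.
#' @param level Significance level for the verdict (default 0.05).
#' @return A `curve_comparison`: list with `method = "delong_paired"`, `auc_a`,
#'   `auc_b`, `z`, `p`, `verdict` ("a_better", "b_better" or "equal").
#' @export
delong_paired_test <- function(scores_a, scores_b, is_case = NULL,
                               level = 0.05) {
  if (is.null(is_case)) {
    stopifnot(identical(scores_a$child_id, scores_b$child_id),
              identical(scores_a$is_case, scores_b$is_case))
    is_case <- scores_a$is_case
    a <- scores_a$score; b <- scores_b$score
  } else {
    a <- as.numeric(scores_a); b <- as.numeric(scores_b)
    stopifnot(length(a) == length(b), length(is_case) == length(a))
  }
  da <- delong_components(a[is_case], a[!is_case])
  db <- delong_components(b[is_case], b[!is_case])
  m <- sum(is_case); n <- sum(!is_case)
  var_diff <- stats::var(da$v10 - db$v10) / m + stats::var(da$v01 - db$v01) / n
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (abs(da$auc - db$auc) > 0) {
      warning("degenerate DeLong variance; curves reported as equal",
              call. = FALSE)
    }
    return(structure(list(method = "delong_paired", auc_a = da$auc,
                          auc_b = db$auc, z = if (da$auc == db$auc) 0 else NA_real_,
                          p = 1, verdict = "equal"),
                     class = "curve_comparison"))
  }
  z <- (da$auc - db$auc) / sqrt(var_diff)
  p <- 2 * stats::pnorm(-abs(z))
  verdict <- if (p >= level) "equal" else if (z > 0) "a_better" else "b_better"
  structure(list(method = "delong_paired", auc_a = da$auc, auc_b = db$auc,
                 z = z, p = p, verdict = verdict),
            class = "curve_comparison")
}

#' Hanley-McNeil standard error of an AUC
#'
#' Uses Q1 = A/(2-A) and Q2 = 2A^2/(1+A).
#'
#' @param auc AUC value.
#' @param n_cases,n_controls Group sizes.
#' @return Approximate standard error.
#' @export
hanley_mcneil_se <- function(auc, n_cases, n_controls) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
          (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls))
}

#' Hanley-McNeil comparison of two independent ROC curves
#'
#' For AUCs computed on samples with different case/control definitions
#' (e.g., an ASD subscale versus a DSM-oriented subscale with its own
#' disorder group).
#'
#' @param roc_a,roc_b `roc_result` objects from independent samples.
#' @param level Significance level for the verdict.
#' @return A `curve_comparison` with `method = "hanley_mcneil_independent"`.
#' @export
hanley_mcneil_independent_test <- function(roc_a, roc_b, level = 0.05) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  se_a <- hanley_mcneil_se(roc_a$auc, roc_a$n_cases, roc_a$n_controls)
  se_b <- hanley_mcneil_se(roc_b$auc, roc_b$n_cases, roc_b$n_controls)
  denom <- sqrt(se_a^2 + se_b^2)
  if (!is.finite(denom) || denom <= 0) {
    stop("both standard errors are zero; comparison undefined", call. = FALSE)
  }
  z <- (roc_a$auc - roc_b$auc) / denom
  p <- 2 * stats::pnorm(-abs(z))
  verdict <- if (p >= level) "equal" else if (z > 0) "a_better" else "b_better"
  structure(list(method = "hanley_mcneil_independent", auc_a = roc_a$auc,
                 auc_b = roc_b$auc, z = z, p = p, verdict = verdict),
            class = "curve_comparison")
}

#' @export
#' @method print curve_comparison
print.curve_comparison <- function(x, ...) {
  cat(sprintf("%s: AUC %.3f vs %.3f, z = %.3f, p = %.4g (%s)\n",
              x$method, x$auc_a, x$auc_b, x$z, x$p, x$verdict))
  invisible(x)
}

#' Sensitivity and specificity at a cut-off
#'
#' Positive classification at score >= cutoff.
#'
#' @param scores A `scale_score_table` or data.frame with `score`, `is_case`.
#' @param cutoff Threshold.
#' @return Named numeric vector `c(sensitivity=, specificity=)`.
#' @export
sens_spec_at_cutoff <- function(scores, cutoff) {
  sp <- split_scores(scores)
  c(sensitivity = mean(sp$cases >= cutoff),
    specificity = mean(sp$controls < cutoff))
}

# Candidate thresholds: midpoints between adjacent distinct observed scores,
# plus -Inf and +Inf.
candidate_thresholds <- function(values) {
  v <- sort(unique(values))
  if (length(v) < 2) return(c(-Inf, Inf))
  c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
}

choose_cutoffs_one <- function(cases, controls, target_sensitivity = 0.80,
                               clinical_rule = c("youden", "closest")) {
  clinical_rule <- match.arg(clinical_rule)
  th <- candidate_thresholds(c(cases, controls))
  sens <- vapply(th, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(th, function(t) mean(controls < t), numeric(1))
  ok <- sens >= target_sensitivity
  sub_i <- max(which(ok))  # -Inf always qualifies (sens = 1)
  crit <- if (clinical_rule == "youden") sens + spec - 1 else -abs(sens - spec)
  clin_i <- which.max(crit)  # which.max takes the first (lowest) on ties
  list(subclinical_cutoff = th[sub_i],
       subclinical_sens = sens[sub_i], subclinical_spec = spec[sub_i],
       clinical_cutoff = th[clin_i],
       clinical_sens = sens[clin_i], clinical_spec = spec[clin_i])
}

#' Stratified subclinical and clinical cut-offs
#'
#' Per gender-by-age-band stratum, the subclinical cut-off is the largest
#' candidate threshold with sensitivity at or above `target_sensitivity`
#' (screening-oriented: high sensitivity); the clinical cut-off maximizes
#' Youden's J = sensitivity + specificity - 1 (ties broken toward the lower
#' threshold, favoring sensitivity). `clinical_rule = "closest"` instead
#' minimizes |sensitivity - specificity|. Pooled sensitivity/specificity apply
#' each stratum's cut-offs to its own children, then pool the classifications.
#'
#' @param scores A `scale_score_table`.
#' @param target_sensitivity Subclinical sensitivity target (default 0.80).
#' @param stratify Stratify by gender x age band (default TRUE).
#' @param clinical_rule "youden" (default) or "closest".
#' @return A `cutoff_table` data.frame (one row per stratum with cut-offs and
#'   their sensitivity/specificity); attribute `pooled` holds the pooled
#'   sensitivity/specificity at subclinical and clinical cut-offs.
#' @export
choose_cutoffs <- function(scores, target_sensitivity = 0.80, stratify = TRUE,
                           clinical_rule = c("youden", "closest")) {
  clinical_rule <- match.arg(clinical_rule)
  strata <- if (stratify) {
    split(scores, list(scores$gender, scores$age_band), drop = TRUE)
  } else list(all = scores)
  rows <- list(); pooled <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    cases <- s$score[s$is_case]; controls <- s$score[!s$is_case]
    if (!length(cases) || !length(controls)) {
      warning("stratum '", nm, "' lacks cases or controls; omitted",
              call. = FALSE)
      next
    }
    cc <- choose_cutoffs_one(cases, controls, target_sensitivity, clinical_rule)
    rows[[nm]] <- data.frame(
      stratum = nm,
      gender = if (stratify) s$gender[1] else NA_character_,
      age_band = if (stratify) s$age_band[1] else NA_character_,
      n_cases = length(cases), n_controls = length(controls),
      as.data.frame(cc), stringsAsFactors = FALSE
    )
    pooled[[nm]] <- data.frame(
      is_case = s$is_case,
      sub_pos = s$score >= cc$subclinical_cutoff,
      clin_pos = s$score >= cc$clinical_cutoff
    )
  }
  if (!length(rows)) stop("no stratum had both cases and controls", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pl <- do.call(rbind, pooled)
  attr(out, "pooled") <- c(
    subclinical_sensitivity = mean(pl$sub_pos[pl$is_case]),
    subclinical_specificity = mean(!pl$sub_pos[!pl$is_case]),
    clinical_sensitivity = mean(pl$clin_pos[pl$is_case]),
    clinical_specificity = mean(!pl$clin_pos[!pl$is_case])
  )
  attr(out, "target_sensitivity") <- target_sensitivity
  class(out) <- c("cutoff_table", "data.frame")
  out
}
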