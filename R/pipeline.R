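#' Development and cross-validation pipeline
#'
#' `run_development()` executes the full construction-and-validation sequence
#' on a development cohort: per-item mixed models over all items, the
#' data-driven and clinician-expert selection rules, then scoring,
#' reliability, ROC and stratified cut-off construction for every requested
#' subscale. `run_cross_validation()` applies frozen subscales and
#' development-derived cut-offs to an independent cohort without any
#' re-selection or cut-off refitting (re-deriving cut-offs is available only
#' behind an explicit flag, for sensitivity analysis).
#'
#' @name pipeline
NULL

validate_one_subscale <- function(cohort, subscale, case_groups,
                                  target_sensitivity, cutoffs = NULL) {
  scores <- score_scale(cohort, subscale, case_groups = case_groups)
  mat <- item_score_matrix(cohort, subscale)
  rel <- cronbach_alpha(mat)
  roc <- roc_auc(scores)
  refit <- is.null(cutoffs)
  if (refit) {
    cutoffs <- choose_cutoffs(scores, target_sensitivity = target_sensitivity)
    perf <- attr(cutoffs, "pooled")
  } else {
    perf <- apply_cutoffs(scores, cutoffs)
  }
  list(scores = scores, reliability = rel, roc = roc, cutoffs = cutoffs,
       performance = perf,
       summary = data.frame(
         subscale = subscale$name, k = length(subscale),
         alpha = rel$alpha, alpha_band = rel$band,
         auc = roc$auc, auc_se = roc$se,
         auc_ci_lo = roc$ci95[1], auc_ci_hi = roc$ci95[2],
         auc_band = roc$band,
         subclinical_sensitivity = unname(perf["subclinical_sensitivity"]),
         subclinical_specificity = unname(perf["subclinical_specificity"]),
         clinical_sensitivity = unname(perf["clinical_sensitivity"]),
         clinical_specificity = unname(perf["clinical_specificity"]),
         cutoffs_refit = refit,
         stringsAsFactors = FALSE))
}

#' Apply previously established stratified cut-offs to new scores
#'
#' @param scores A `scale_score_table`.
#' @param cutoffs A `cutoff_table` learned elsewhere (e.g., on the
#'   development sample). Strata are matched by gender and age band; children
#'   in strata absent from the table are skipped with a warning.
#' @return Pooled sensitivity/specificity at the subclinical and clinical
#'   cut-offs (named numeric vector).
#' @export
apply_cutoffs <- function(scores, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_table"))
  key <- paste(scores$gender, scores$age_band, sep = ".")
  ck <- paste(cutoffs$gender, cutoffs$age_band, sep = ".")
  hit <- match(key, ck)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " child(ren) in strata without established ",
            "cut-offs skipped", call. = FALSE)
  }
  keep <- !is.na(hit)
  s <- scores[keep, , drop = FALSE]; hit <- hit[keep]
  sub_pos <- s$score >= cutoffs$subclinical_cutoff[hit]
  clin_pos <- s$score >= cutoffs$clinical_cutoff[hit]
  c(subclinical_sensitivity = mean(sub_pos[s$is_case]),
    subclinical_specificity = mean(!sub_pos[!s$is_case]),
    clinical_sensitivity = mean(clin_pos[s$is_case]),
    clinical_specificity = mean(!clin_pos[!s$is_case]))
}

#' Run the development stage
#'
#' @param cohort Development `cohort`.
#' @param registry An [load_registry()] result supplying the subscales to
#'   validate alongside the newly constructed ones.
#' @param selection A [selection_config()].
#' @param clinician_ratings Optional binary ratings matrix for the
#'   clinician-expert rule (see [generate_clinician_ratings()]).
#' @param validate Names of registry subscales to validate (default: the
#'   screening subscales packaged in the registry, minus the two that are
#'   being re-derived here).
#' @param case_groups Groups counted as cases (default "ASD").
#' @param target_sensitivity Subclinical sensitivity target.
#' @return A `development_result`: list with `data_driven` and
#'   `clinician_expert` [subscale_definition()]s (the latter NULL without
#'   ratings), `fits`, `verdicts`, `audit` (flattened fits table with verdict
#'   counts), `validation` (per-subscale results incl. cut-off tables), and
#'   `report` (one summary row per subscale).
#' @export
run_development <- function(cohort, registry = load_registry(),
                            selection = selection_config(),
                            clinician_ratings = NULL,
                            validate = NULL,
                            case_groups = "ASD",
                            target_sensitivity = 0.80) {
  fits <- fit_all_items(cohort)
  verdicts <- lapply(fits, compare_to_groups, alpha = selection$alpha)
  failed <- vapply(fits, function(f) !f$converged, logical(1))
  if (any(failed)) {
    warning(sum(failed), " item model(s) failed to converge and were ",
            "excluded from selection: ",
            paste(names(fits)[failed], collapse = ", "), call. = FALSE)
  }
  data_driven <- select_items_data_driven(verdicts, selection)
  clinician_expert <- if (!is.null(clinician_ratings)) {
    select_items_clinician(clinician_ratings, selection)
  }

  if (is.null(validate)) {
    validate <- setdiff(names(registry$subscales),
                        c("DataDriven", "ClinicianExpert"))
  }
  to_validate <- registry$subscales[validate]
  to_validate$DataDriven <- data_driven
  if (!is.null(clinician_expert)) to_validate$ClinicianExpert <- clinician_expert
  to_validate <- Filter(function(s) length(s) > 0, to_validate)

  validation <- lapply(to_validate, function(s) {
    validate_one_subscale(cohort, s, case_groups, target_sensitivity)
  })
  report <- do.call(rbind, lapply(validation, `[[`, "summary"))
  rownames(report) <- NULL

  audit <- fits_table(fits)
  nsig <- vapply(verdicts, `[[`, integer(1), "n_significant")
  audit$n_significant <- nsig[as.character(audit$item_id)]
  audit$selected <- audit$item_id %in% data_driven$item_ids

  structure(list(data_driven = data_driven,
                 clinician_expert = clinician_expert,
                 fits = fits, verdicts = verdicts, audit = audit,
                 validation = validation, report = report,
                 selection = selection, case_groups = case_groups),
            class = "development_result")
}

#' @export
#' @method print development_result
print.development_result <- function(x, ...) {
  cat(sprintf("<development run: data-driven subscale %d items%s>\n",
              length(x$data_driven),
              if (is.null(x$clinician_expert)) ""
              else sprintf(", clinician-expert %d items",
                           length(x$clinician_expert))))
  print(x$report[, c("subscale", "k", "alpha", "auc", "auc_band")])
  invisible(x)
}

#' Validate frozen subscales on a cross-validation cohort
#'
#' @param cohort Cross-validation `cohort`.
#' @param subscales Named list of frozen [subscale_definition()]s.
#' @param dev_cutoffs Named list of `cutoff_table`s from the development run
#'   (matching `subscales` names); required unless `refit_cutoffs = TRUE`.
#' @param case_groups Groups counted as cases.
#' @param target_sensitivity Used only when refitting cut-offs.
#' @param refit_cutoffs Re-derive cut-offs on this cohort (sensitivity
#'   analysis only; default FALSE applies the development cut-offs).
#' @return A `crossval_result`: list with `validation` (per subscale) and
#'   `report` (summary rows; `cutoffs_refit` records which rule applied).
#' @export
run_cross_validation <- function(cohort, subscales, dev_cutoffs = NULL,
                                 case_groups = "ASD",
                                 target_sensitivity = 0.80,
                                 refit_cutoffs = FALSE) {
  if (!length(subscales)) {
    return(structure(list(validation = list(),
                          report = data.frame()), class = "crossval_result"))
  }
  if (!refit_cutoffs && is.null(dev_cutoffs)) {
    stop("dev_cutoffs are required: cross-validation applies development ",
         "cut-offs (set refit_cutoffs = TRUE only for sensitivity analysis)",
         call. = FALSE)
  }
  validation <- lapply(names(subscales), function(nm) {
    co <- if (refit_cutoffs) NULL else dev_cutoffs[[nm]]
    if (!refit_cutoffs && is.null(co)) {
      stop("no development cut-offs supplied for subscale '", nm, "'",
           call. = FALSE)
    }
    validate_one_subscale(cohort, subscales[[nm]], case_groups,
                          target_sensitivity, cutoffs = co)
  })
  names(validation) <- names(subscales)
  report <- do.call(rbind, lapply(validation, `[[`, "summary"))
  rownames(report) <- NULL
  structure(list(validation = validation, report = report),
            class = "crossval_result")
}

#' Pairwise DeLong comparisons among subscales scored on one sample
#'
#' @param validation The `validation` element of a development or
#'   cross-validation result (each entry carrying `scores`).
#' @param level Significance level for verdicts.
#' @return data.frame: `subscale_a`, `subscale_b`, `auc_a`, `auc_b`, `z`, `p`,
#'   `verdict`.
#' @export
compare_subscales_paired <- function(validation, level = 0.05) {
  nms <- names(validation)
  if (length(nms) < 2) return(data.frame())
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    cmp <- delong_paired_test(validation[[pr[1]]]$scores,
                              validation[[pr[2]]]$scores, level = level)
    data.frame(subscale_a = pr[1], subscale_b = pr[2],
               auc_a = cmp$auc_a, auc_b = cmp$auc_b, z = cmp$z, p = cmp$p,
               verdict = cmp$verdict, stringsAsFactors = FALSE)
  }))
}

#' Write a report bundle to disk
#'
#' Emits `report.csv` (per-subscale summary), `audit.csv` (per-item selection
#' audit, development runs only), `cutoffs_<subscale>.csv` per subscale, and
#' `comparisons.csv` (pairwise DeLong matrix).
#'
#' @param result A `development_result` or `crossval_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$report, file.path(dir, "report.csv"),
                   row.names = FALSE)
  if (!is.null(result$audit)) {
    utils::write.csv(result$audit, file.path(dir, "audit.csv"),
                     row.names = FALSE)
  }
  for (nm in names(result$validation)) {
    ct <- result$validation[[nm]]$cutoffs
    utils::write.csv(as.data.frame(ct),
                     file.path(dir, paste0("cutoffs_", nm, ".csv")),
                     row.names = FALSE)
  }
  cmp <- compare_subscales_paired(result$validation)
  utils::write.csv(cmp, file.path(dir, "comparisons.csv"), row.names = FALSE)
  invisible(dir)
}
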