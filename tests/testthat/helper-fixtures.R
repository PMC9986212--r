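# Shared fixtures built in code.

# A reduced 11-group configuration for fast unit tests.
small_groups <- function(scale = 1) {
  round(scale * c(ASD = 60, ADHD = 80, Anxiety = 40, PTSD = 30, Affective = 30,
                  OCD = 30, Behavioral = 30, DisorderNOS = 30, OtherDSM = 30,
                  NoClassification = 30, TD = 30))
}

small_cohort <- function(item_ids = 1:20, planted = c(1, 5, 9, 17), seed = 42,
                         ...) {
  generate_cohort(cohort_config(n_per_group = small_groups(),
                                item_ids = item_ids, planted_items = planted,
                                seed = seed, ...))
}

# Hand-built cohort for exact scoring arithmetic.
manual_cohort <- function(responses, children) {
  structure(list(responses = responses, children = children,
                 planted_items = integer(0), config = NULL),
            class = "cohort")
}

# Minimal score table for ROC tests.
make_scores <- function(cases, controls, gender = "boy", age_band = "child") {
  n <- length(cases) + length(controls)
  structure(data.frame(
    child_id = seq_len(n),
    score = c(cases, controls),
    group = rep(c("ASD", "CG"), c(length(cases), length(controls))),
    is_case = rep(c(TRUE, FALSE), c(length(cases), length(controls))),
    gender = rep_len(gender, n),
    age_band = rep_len(age_band, n),
    n_informants = 2L,
    stringsAsFactors = FALSE
  ), class = c("scale_score_table", "data.frame"))
}

# Fabricated model fit carrying chosen contrasts, for verdict-rule tests.
fake_fit <- function(item_id, estimates, pvals,
                     groups = paste0("G", seq_along(estimates))) {
  structure(list(
    item_id = item_id, beta = estimates, se = rep(1, length(estimates)),
    contrasts = data.frame(group = groups, estimate = estimates,
                           se = rep(1, length(estimates)),
                           z = estimates, p = pvals,
                           stringsAsFactors = FALSE),
    tau2 = 0.1, sigma2 = 1, n_children = 100L, n_rows = 180L,
    converged = TRUE, messages = character(0)
  ), class = "item_model_fit")
}

fake_verdict <- function(item_id, n_significant, n_groups = 10,
                         converged = TRUE) {
  flags <- rep(FALSE, n_groups)
  if (n_significant > 0) flags[seq_len(n_significant)] <- TRUE
  structure(list(item_id = as.integer(item_id),
                 verdicts = data.frame(group = paste0("G", seq_len(n_groups)),
                                       asd_higher_significant = flags),
                 n_significant = as.integer(n_significant),
                 converged = converged),
            class = "comparison_verdicts")
}
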