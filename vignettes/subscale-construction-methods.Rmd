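---
title: "Methods: constructing and validating ASD screening subscales from a CBCL-type inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and validating ASD screening subscales from a CBCL-type inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific problem

The Child Behavior CheckList for ages 6–18 (CBCL 6-18) is a broadband
parent-rated inventory of 120 problem items, each scored 0 (not true),
1 (somewhat or sometimes true) or 2 (very true or often true). It is routinely
collected at intake in child mental-health care, but it contains no dedicated
autism-spectrum-disorder (ASD) scale. A recurring research programme therefore
asks: can a *subset* of CBCL items act as an ASD screener, so that already
collected questionnaires flag children who should receive a full (and
expensive) diagnostic work-up?

`cbclscreen` implements the complete methodology for that question:

1. an **item registry** holding the candidate subscales and their set algebra
   (sizes, pairwise overlaps, syndrome composition);
2. a **synthetic cohort generator** producing multi-informant ordinal item
   data with planted group effects, so every statistical routine can be
   exercised against a known ground truth;
3. per-item **informant-nested linear mixed models** comparing an ASD group
   with each comparison group;
4. two **item-selection rules** — a data-driven significance-vote rule and a
   clinician-expert panel-vote rule;
5. **psychometrics** (raw-sum scoring with informant averaging, Cronbach's
   alpha) and **diagnostic accuracy** (DeLong AUC inference, paired and
   independent curve comparisons, stratified cut-offs);
6. a **pipeline** separating development (selection + cut-off derivation)
   from cross-validation (frozen subscales, frozen cut-offs).

No real CBCL data ships with the package; clinical item-level data cannot be
redistributed. All stochastic demonstrations run on the synthetic generator.

## The item registry

`load_registry()` returns the packaged 120-item table. Each item carries its
2001-revision syndrome-scale assignment (Withdrawn/Depressed, Thought
Problems, Social Problems, Attention Problems, Anxious/Depressed, Aggressive
Behavior, Rule-Breaking, Somatic Complaints, Other Problems, or none) and 0/1
membership flags for nine subscales:

* the three ASD-relevant syndrome scales and their unions (`WTP` =
  Withdrawn/Depressed ∪ Thought Problems, 23 items; `ASDProfile` = those two
  ∪ Social Problems, 34 items);
* two previously proposed ASD item sets from the screening literature (`Ooi`,
  9 items; `So`, 10 items);
* the two subscales this methodology derives: `DataDriven` (15 items) and
  `ClinicianExpert` (23 items), overlapping in 12 items.

`load_registry()` re-validates every structural invariant on load (unique
IDs, legal syndrome labels, binary flags, union identities), so a corrupted
registry file cannot silently propagate.

## Synthetic cohort generator

`generate_cohort()` draws a latent-Normal threshold model. For child $c$ in
diagnostic group $g$, informant $r$ (mother/father) and item $j$:

$$
L_{crj} = \delta\,\mathbf{1}[g = \text{ASD}]\,\mathbf{1}[j \in P]
        + \beta_{\text{age}}(a_c - \bar a) + \beta_{\text{sex}}\,\text{girl}_c
        + u_c + \varepsilon_{crj},
$$

with $u_c \sim N(0, \tau^2)$ (child random intercept shared across
informants and items) and $\varepsilon_{crj} \sim N(0, \sigma^2)$. The
observed ordinal score is the number of thresholds $(t_1, t_2)$ the latent
value exceeds, giving the CBCL's 0/1/2 coding. $P$ is the planted item set —
the ground truth a selection rule should recover.

### Default parameters and their rationale

All defaults were fixed *a priori*, before any test outcome was inspected,
and are frozen as the package's reference conditions:

* **Group sizes** (total 1666 children, 11 groups: ASD 270, ADHD 724,
  anxiety-related 203, PTSD 91, affective 61, OCD 56, behavioral 34,
  disorder-NOS 52, other-DSM 69, no classification 65, typically developing
  41) mirror the composition of a large naturalistic outpatient intake
  sample, including its heavy imbalance: the smallest comparison group has
  only 34 children, which is exactly what stresses a rule demanding
  significance against 7 of 10 comparison groups.
* **Informant availability**: mother ratings present with probability 0.97,
  father ratings 0.78, independently; a child with neither draw is assigned
  the mother. This reproduces the common pattern that nearly all children
  have a maternal rating and roughly three quarters a paternal one, and makes
  the informant-nesting of the mixed model consequential.
* **Planted effect $\delta = 1.5$** (latent SD units) with thresholds
  $(0.5, 1.5)$, $\tau = 0.5$, $\sigma = 1$. A pre-registered power
  calculation drove this choice: the implied per-item score difference
  between ASD and a null group is about 0.5 raw points against a residual
  score SD near 0.7, so the Wald statistic for the *smallest* comparison
  group ($n = 34$) has expectation $\approx 7$; even at $\alpha = 0.001$
  against 7-of-10 groups the planted-set recovery probability is effectively
  1, while null items (true shift 0) are flagged at $\approx 5 \times
  10^{-4}$ per contrast. Recovery failures in tests therefore indicate code
  defects, not bad luck.
* **Covariates**: ages uniform on 6–18, 37% girls, small age slope and sex
  shift so the fixed-effect adjustments in the mixed model are non-trivial.

### Generator realism and limitations

The generator reproduces the *structural* features that matter to the
methodology — ordinal 0/1/2 items, two correlated informants per child,
group imbalance, covariate effects — but not every feature of real data:
item-specific base rates are homogeneous, informants are exchangeable (no
systematic mother/father effect), and inter-item correlation arises solely
through the shared child intercept. These simplifications are intentional:
they keep every test's ground truth analytically available.

## Per-item mixed models and the data-driven rule

For each item, `fit_item_model()` fits

$$
\text{score} \sim \text{group} + \text{age}_c + \text{girl} + (1 \mid \text{child}),
$$

by REML (via `lme4`), with ASD as the reference level, on the long
child-by-informant data. Each comparison group's contrast (group minus ASD)
gets a two-sided Wald test with a Normal reference distribution.
`compare_to_groups()` flags a group when $p < 0.001$ *and* the contrast is
negative (ASD scoring higher); `select_items_data_driven()` keeps an item
flagged against at least 7 of the 10 comparison groups. Non-converged fits
are conservatively excluded from selection and reported in the audit table.

Numerical choices worth noting:

* A **Normal (not $t$) reference** for the Wald statistic: with ≥ 1600
  children and ≥ 2900 informant rows per item, the degrees-of-freedom
  correction is far below the resolution of an $\alpha = 0.001$ rule; the
  Normal reference keeps the test definition free of the contested choice of
  denominator df in mixed models.
* The model treats the 0/1/2 score as numeric. This matches the original
  analysis strategy for this family of screeners and is the quantity the
  subscale ultimately sums; the acceptance suite confirms the rule's
  operating characteristics (planted recovery, null selection rate) under
  the ordinal generator.

The clinician-expert rule, `select_items_clinician()`, is a pure vote count:
an item enters when at least 11 of 15 panel members flagged it (a 73.33%
criterion, `vote_fraction()`).

## Scoring, reliability, accuracy

`score_scale()` computes, per informant, the raw sum over the subscale's
items (a missing item counts 0; an informant missing more than 10% of the
items is dropped), then averages over a child's available informants.
`cronbach_alpha()` uses the standard $k/(k-1)\,(1 - \sum_i s_i^2 /
s_\text{total}^2)$ form on informant-averaged item scores, with the
conventional 0.50/0.60/0.70/0.80/0.90 interpretation bands.

`roc_auc()` computes the Mann–Whitney AUC (ties count one half) with
DeLong's structural-component variance; `delong_paired_test()` compares two
subscales scored on the *same* children, `hanley_mcneil_independent_test()`
compares curves from independent samples. `choose_cutoffs()` works per
gender-by-age-band stratum (girls/boys × ages 6–11 / 12–18):

* the **subclinical cut-off** is the largest candidate threshold (midpoints
  between adjacent observed scores, plus ±∞) with sensitivity ≥ 0.80 —
  screening-oriented leniency;
* the **clinical cut-off** maximizes Youden's $J$; ties break toward the
  *lower* threshold, again favouring sensitivity over specificity in a
  screening context.

Classification is positive at score ≥ cut-off. One known edge case: under
(near-)perfect separation the Youden optimum can sit above the
sensitivity-targeted threshold, so the "clinical" cut-off is not guaranteed
to be the stricter of the two on extreme synthetic data; both are reported
with their own sensitivity/specificity so the inversion is visible.

## Development versus cross-validation

`run_development()` runs the full sequence on one cohort; its outputs — the
two derived subscales and the stratified cut-off tables — are then *frozen*.
`run_cross_validation()` applies them to independent cohorts and refuses to
run without development cut-offs unless `refit_cutoffs = TRUE` is set
explicitly (a leakage guard; refitting is for sensitivity analysis only).
The acceptance suite demonstrates the expected qualitative behaviour: when
the cross-validation cohort's planted effects are attenuated (half the
development $\delta$), the cross-validation AUC falls below the development
AUC in ≈ 100% of replicates — the screener's accuracy shrinks when the
target population separates less cleanly, exactly the pattern reported for
real replication samples of such screeners.

```{r}
library(cbclscreen)
dev_cohort <- generate_cohort(cohort_config(seed = 1))
dev <- run_development(dev_cohort)
dev$report
cv <- run_cross_validation(
  generate_cohort(cohort_config(seed = 2)),
  subscales = list(DataDriven = dev$data_driven),
  dev_cutoffs = list(DataDriven = dev$validation$DataDriven$cutoffs))
cv$report
```

## Verification strategy

The test suite never compares against hidden constants of unclear origin;
every numeric claim is checked against an explicit independent oracle:

* AUC against brute-force pair counting; DeLong variance against `pROC` and
  against a stratified bootstrap; Cronbach's alpha against the
  covariance-matrix identity (to $10^{-10}$); cut-offs against an exhaustive
  threshold scan.
* The mixed model against OLS in the balanced complete-data limit (where GLS
  and OLS coincide) and against a dense-matrix restricted-likelihood grid.
* Stochastic guarantees at scale: exact planted-set recovery on the default
  cohort; zero selections across 2000 null item fits; paired DeLong type-I
  error within [0.03, 0.07] at nominal 0.05; per-contrast null rejection
  rate ≤ 0.005 at $\alpha = 0.001$; AUC shrinkage under attenuated effects
  in ≥ 90% of 100 replicates.

## Known limitations

* The mixed model assumes Gaussian residuals for an ordinal outcome; this is
  the classical pragmatic choice for CBCL-type analyses, not a generative
  claim. An ordinal mixed model would be the natural extension.
* Hanley–McNeil comparison assumes independent samples and uses the
  negative-exponential variance approximation; it is provided for
  cross-sample comparisons where the paired DeLong test does not apply.
* Cut-off tables are only as fine as the observed score distribution;
  strata with no cases or no controls are dropped with a warning rather
  than extrapolated.
* The generator's informant model has no informant-specific bias term, so
  informant disagreement is pure noise.
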