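test_that("AUC equals the tie-aware pair-counting probability", {
  # exact hand values
  expect_equal(roc_auc(c(3, 1), c(2, 2))$auc, 0.5)
  expect_equal(roc_auc(c(2, 3), c(0, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 1), c(1, 1))$auc, 0.5)

  # brute-force pair counting on random tied integer instances
  set.seed(19)
  for (i in 1:30) {
    cases <- sample(0:6, sample(2:15, 1), replace = TRUE)
    controls <- sample(0:6, sample(2:15, 1), replace = TRUE)
    acc <- 0
    for (x in cases) for (y in controls) {
      acc <- acc + (x > y) + 0.5 * (x == y)
    }
    expect_equal(roc_auc(cases, controls)$auc,
                 acc / (length(cases) * length(controls)), tolerance = 1e-12)
  }
})

test_that("AUC, DeLong variance and paired test agree with pROC", {
  set.seed(23)
  is_case <- rep(c(TRUE, FALSE), c(40, 60))
  a <- round(rnorm(100, mean = ifelse(is_case, 1, 0)), 1)
  b <- round(rnorm(100, mean = ifelse(is_case, 0.4, 0)), 1)

  ra <- roc_auc(a[is_case], a[!is_case])
  pa <- pROC::roc(response = is_case, predictor = a, levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  expect_equal(ra$auc, as.numeric(pROC::auc(pa)), tolerance = 1e-12)
  expect_equal(ra$se^2, pROC::var(pa), tolerance = 1e-10)

  pb <- pROC::roc(response = is_case, predictor = b, levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  ours <- delong_paired_test(a, b, is_case = is_case)
  ref <- pROC::roc.test(pa, pb, method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
})

test_that("paired test is antisymmetric and null on identical curves", {
  set.seed(29)
  is_case <- rep(c(TRUE, FALSE), each = 30)
  a <- rnorm(60, ifelse(is_case, 0.8, 0))
  b <- rnorm(60, ifelse(is_case, 0.3, 0))
  ab <- delong_paired_test(a, b, is_case = is_case)
  ba <- delong_paired_test(b, a, is_case = is_case)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  self <- delong_paired_test(a, a, is_case = is_case)
  expect_identical(self$z, 0)
  expect_identical(self$p, 1)
  expect_identical(self$verdict, "equal")

  # degenerate variance with genuinely different curves warns
  is2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_warning(
    deg <- delong_paired_test(c(1, 1, 0, 0), c(0, 0, 1, 1), is_case = is2),
    "degenerate")
  expect_identical(deg$verdict, "equal")
})

test_that("paired test refuses mismatched score tables", {
  sa <- make_scores(cases = c(3, 4), controls = c(1, 2))
  sb <- make_scores(cases = c(3, 4), controls = c(1, 2))
  sb$child_id <- sb$child_id + 10L
  expect_error(delong_paired_test(sa, sb))
})

test_that("Hanley-McNeil SE matches its closed form and shrinks with n", {
  a <- 0.85; m <- 30; n <- 50
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  manual <- sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) /
                   (m * n))
  expect_equal(hanley_mcneil_se(a, m, n), manual, tolerance = 1e-14)
  expect_lt(hanley_mcneil_se(a, 4 * m, 4 * n), hanley_mcneil_se(a, m, n))

  ra <- roc_auc(rnorm(40, 1), rnorm(60))
  rb <- roc_auc(rnorm(40, 1), rnorm(60))
  cmp <- hanley_mcneil_independent_test(ra, rb)
  manual_z <- (ra$auc - rb$auc) /
    sqrt(hanley_mcneil_se(ra$auc, 40, 60)^2 +
           hanley_mcneil_se(rb$auc, 40, 60)^2)
  expect_equal(cmp$z, manual_z, tolerance = 1e-12)
  expect_equal(cmp$p, 2 * pnorm(-abs(manual_z)), tolerance = 1e-12)
})

test_that("sensitivity and specificity use the score >= cutoff rule", {
  sc <- make_scores(cases = c(2, 5, 5, 7), controls = c(1, 2, 4, 6))
  ss <- sens_spec_at_cutoff(sc, 5)
  expect_equal(unname(ss["sensitivity"]), 3 / 4)
  expect_equal(unname(ss["specificity"]), 3 / 4)
  expect_equal(unname(sens_spec_at_cutoff(sc, -Inf)["sensitivity"]), 1)
  expect_equal(unname(sens_spec_at_cutoff(sc, Inf)["specificity"]), 1)
})

test_that("cut-off rules pick the documented thresholds on a hand example", {
  sc <- make_scores(cases = c(5, 6, 7, 8, 9), controls = c(1, 2, 3, 4, 5))
  ct <- choose_cutoffs(sc, stratify = FALSE)
  # largest threshold still reaching 80% sensitivity is the 5/6 midpoint
  expect_equal(ct$subclinical_cutoff, 5.5)
  expect_equal(ct$subclinical_sens, 0.8)
  expect_equal(ct$subclinical_spec, 1.0)
  # Youden ties (J = 0.8 at both 4.5 and 5.5) break toward the lower cut-off
  expect_equal(ct$clinical_cutoff, 4.5)
  expect_equal(ct$clinical_sens, 1.0)
  expect_equal(ct$clinical_spec, 0.8)
})

test_that("cut-offs agree with an exhaustive scan on random instances", {
  set.seed(37)
  for (i in 1:40) {
    cases <- sample(0:10, sample(5:20, 1), replace = TRUE)
    controls <- sample(0:10, sample(5:20, 1), replace = TRUE)
    sc <- make_scores(cases, controls)
    ct <- choose_cutoffs(sc, target_sensitivity = 0.8, stratify = FALSE)
    th <- c(-Inf, (sort(unique(c(cases, controls)))[-1] +
                     rev(rev(sort(unique(c(cases, controls))))[-1])) / 2, Inf)
    sens <- sapply(th, function(t) mean(cases >= t))
    spec <- sapply(th, function(t) mean(controls < t))
    expect_equal(ct$subclinical_cutoff, max(th[sens >= 0.8]))
    j <- sens + spec - 1
    expect_equal(ct$clinical_cutoff, th[which(j == max(j))[1]])
  }
})

test_that("stratified cut-offs are per-stratum and pool correctly", {
  boys <- make_scores(cases = c(6, 7, 8, 9, 10), controls = c(1, 2, 3, 4, 5),
                      gender = "boy")
  girls <- make_scores(cases = c(3, 4, 5, 6, 7), controls = c(0, 1, 1, 2, 2),
                       gender = "girl")
  girls$child_id <- girls$child_id + 100L
  both <- rbind(boys, girls)
  class(both) <- class(boys)
  ct <- choose_cutoffs(both)
  expect_identical(nrow(ct), 2L)
  boy_row <- ct[ct$gender == "boy", ]
  girl_row <- ct[ct$gender == "girl", ]
  expect_equal(boy_row$clinical_cutoff,
               choose_cutoffs(boys, stratify = FALSE)$clinical_cutoff)
  expect_equal(girl_row$clinical_cutoff,
               choose_cutoffs(girls, stratify = FALSE)$clinical_cutoff)

  pooled <- attr(ct, "pooled")
  manual_sens <- mean(c(boys$score[boys$is_case] >= boy_row$clinical_cutoff,
                        girls$score[girls$is_case] >= girl_row$clinical_cutoff))
  expect_equal(unname(pooled["clinical_sensitivity"]), manual_sens)

  # a stratum without controls is dropped with a warning
  cases_only <- make_scores(cases = c(5, 6), controls = numeric(0),
                            gender = "boy", age_band = "adolescent")
  cases_only$child_id <- cases_only$child_id + 500L
  with_bad <- rbind(both, cases_only)
  class(with_bad) <- class(both)
  expect_warning(ct2 <- choose_cutoffs(with_bad), "lacks cases or controls")
  expect_identical(nrow(ct2), 2L)
  expect_error(suppressWarnings(choose_cutoffs(cases_only)), "no stratum")
})

test_that("AUC bands and confidence intervals behave at the boundaries", {
  expect_identical(auc_band(c(0.69, 0.70, 0.79, 0.80, 0.89, 0.90, 1.0)),
                   c("poor", "fair", "fair", "good", "good", "excellent",
                     "excellent"))
  ci <- roc_auc(c(9, 10, 11), c(1, 2, 3))$ci95
  expect_gte(ci[1], 0)
  expect_identical(ci[2], 1)
})
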