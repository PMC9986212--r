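# Independent restricted log-likelihood oracle for the random-intercept model,
# evaluated with dense matrices (small instances only).
reml_loglik <- function(y, X, child, tau2, sigma2) {
  Z <- outer(child, unique(child), `==`) + 0
  V <- sigma2 * diag(length(y)) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1]
}

complete_cohort <- function(seed = 11, groups = small_groups(), ...) {
  generate_cohort(cohort_config(
    n_per_group = groups, item_ids = 1, planted_items = 1,
    mother_present_prob = 1, father_present_prob = 1, seed = seed, ...))
}

test_that("with complete balanced informants the fit reduces to OLS", {
  # cluster-constant covariates + equal cluster sizes make GLS and OLS agree
  coh <- complete_cohort(seed = 31)
  fit <- fit_item_model(coh, 1)
  dat <- merge(coh$responses, coh$children, by = "child_id")
  dat$group <- relevel(factor(dat$group), ref = "ASD")
  dat$age_c <- dat$age - mean(dat$age)
  dat$girl <- as.integer(dat$gender == "girl")
  ols <- lm(score ~ group + age_c + girl, data = dat)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("balanced two-group contrast equals difference of child-mean scores", {
  coh <- generate_cohort(cohort_config(
    n_per_group = c(ASD = 40, TD = 40), item_ids = 1, planted_items = 1,
    delta = 1, age_range = c(10, 10), p_girl = 0,
    mother_present_prob = 1, father_present_prob = 1, seed = 13))
  fit <- fit_item_model(coh, 1)
  dat <- merge(coh$responses, coh$children, by = "child_id")
  child_means <- tapply(dat$score, dat$child_id, mean)
  grp <- coh$children$group[match(as.integer(names(child_means)),
                                  coh$children$child_id)]
  diff_means <- mean(child_means[grp == "TD"]) - mean(child_means[grp == "ASD"])
  expect_equal(fit$contrasts$estimate[fit$contrasts$group == "TD"],
               diff_means, tolerance = 1e-8)
})

test_that("returned variance components maximise the restricted likelihood", {
  coh <- generate_cohort(cohort_config(
    n_per_group = c(ASD = 15, TD = 15), item_ids = 1, planted_items = 1,
    delta = 1, tau = 0.6, sigma = 0.9,
    mother_present_prob = 0.9, father_present_prob = 0.8, seed = 21))
  fit <- fit_item_model(coh, 1)
  dat <- merge(coh$responses, coh$children, by = "child_id")
  dat$group <- relevel(factor(dat$group), ref = "ASD")
  dat$age_c <- dat$age - mean(dat$age)
  dat$girl <- as.integer(dat$gender == "girl")
  X <- model.matrix(~ group + age_c + girl, dat)
  at_hat <- reml_loglik(dat$score, X, dat$child_id, fit$tau2, fit$sigma2)
  grid <- expand.grid(tau2 = seq(0.001, 1.2, length.out = 18),
                      sigma2 = seq(0.05, 1.5, length.out = 18))
  on_grid <- mapply(function(t2, s2) reml_loglik(dat$score, X, dat$child_id,
                                                 t2, s2),
                    grid$tau2, grid$sigma2)
  expect_gte(at_hat, max(on_grid) - 1e-4)
})

test_that("estimates are invariant to row order and informant relabeling", {
  coh <- small_cohort(item_ids = 1, planted = 1, seed = 44)
  fit <- fit_item_model(coh, 1)

  shuffled <- coh
  set.seed(1)
  shuffled$responses <- shuffled$responses[sample(nrow(shuffled$responses)), ]
  expect_equal(fit_item_model(shuffled, 1)$beta, fit$beta, tolerance = 1e-8)

  relabeled <- coh
  relabeled$responses$informant <-
    ifelse(relabeled$responses$informant == "mother", "father", "mother")
  expect_equal(fit_item_model(relabeled, 1)$beta, fit$beta, tolerance = 1e-10)
})

test_that("adding a constant to every score shifts only the intercept", {
  coh <- small_cohort(item_ids = 1, planted = 1, seed = 45)
  fit <- fit_item_model(coh, 1)
  shifted <- coh
  shifted$responses$score <- shifted$responses$score + 3
  fit2 <- fit_item_model(shifted, 1)
  expect_equal(unname(fit2$beta[1]), unname(fit$beta[1]) + 3, tolerance = 1e-6)
  expect_equal(fit2$beta[-1], fit$beta[-1], tolerance = 1e-6)
  expect_equal(fit2$contrasts$p, fit$contrasts$p, tolerance = 1e-6)
})

test_that("Wald p-values track a likelihood-ratio oracle at large n", {
  coh <- generate_cohort(cohort_config(
    n_per_group = c(ASD = 400, TD = 400), item_ids = 1, planted_items = 1,
    delta = 0.08, seed = 52))
  fit <- fit_item_model(coh, 1, reml = FALSE)
  dat <- merge(coh$responses, coh$children, by = "child_id")
  dat$group <- relevel(factor(dat$group), ref = "ASD")
  dat$age_c <- dat$age - mean(dat$age)
  dat$girl <- as.integer(dat$gender == "girl")
  full <- lme4::lmer(score ~ group + age_c + girl + (1 | child_id),
                     data = dat, REML = FALSE)
  null <- lme4::lmer(score ~ age_c + girl + (1 | child_id),
                     data = dat, REML = FALSE)
  lrt_p <- pchisq(2 * (logLik(full) - logLik(null)), df = 1,
                  lower.tail = FALSE)
  expect_lt(abs(fit$contrasts$p[1] - lrt_p), 0.05)
})

test_that("verdict rule combines significance and direction", {
  # group-minus-ASD estimate negative means ASD scored higher
  fit <- fake_fit(1, estimates = c(-0.5, 0.5, -0.5),
                  pvals = c(0.0009, 0.0009, 0.01))
  v <- compare_to_groups(fit, alpha = 0.001)
  expect_identical(v$verdicts$asd_higher_significant, c(TRUE, FALSE, FALSE))
  expect_identical(v$n_significant, 1L)

  all_sig <- fake_fit(2, estimates = rep(-1, 10), pvals = rep(1e-6, 10))
  expect_identical(compare_to_groups(all_sig)$n_significant, 10L)

  unconverged <- fake_fit(3, estimates = rep(-1, 10), pvals = rep(1e-6, 10))
  unconverged$converged <- FALSE
  expect_identical(compare_to_groups(unconverged)$n_significant, 0L)
})

test_that("missing reference group is an error", {
  coh <- generate_cohort(cohort_config(n_per_group = c(ASD = 10, TD = 10),
                                       item_ids = 1, planted_items = 1,
                                       seed = 2))
  coh$children$group[coh$children$group == "ASD"] <- "Other"
  expect_error(fit_item_model(coh, 1), "reference group")
})
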