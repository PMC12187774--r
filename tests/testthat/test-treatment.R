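test_that("dichotomization reproduces the arm-median worked examples", {
  rule <- dichotomization_rule()
  # treatment-arm medians: high fluid balance, zero norepinephrine
  expect_identical(dichotomize(5.19, 0.00, rule), 1L)
  # control-arm medians: low fluid balance, moderate norepinephrine
  expect_identical(dichotomize(1.74, 0.04, rule), 0L)
  # a point exactly on the line goes to control
  expect_identical(dichotomize(2.0, 0.0, rule), 0L)
  expect_error(dichotomize(Inf, 0, rule), "finite")
})

test_that("dichotomization is monotone in NE and in the offset", {
  set.seed(41)
  tifb <- runif(200, 0, 8); ne <- runif(200, 0, 0.15)
  rule <- dichotomization_rule()
  base <- dichotomize(tifb, ne, rule)
  # raising NE never moves a patient into the treatment arm
  expect_true(all(dichotomize(tifb, ne + 0.01, rule) <= base))
  # raising the offset never shrinks the treatment arm
  for (off in c(-0.12, -0.08, -0.04, 0, 0.04, 0.08)) {
    r_lo <- dichotomization_rule(offset = off, offset_grid = off)
    r_hi <- dichotomization_rule(offset = off + 0.04, offset_grid = off + 0.04)
    expect_gte(sum(dichotomize(tifb, ne, r_hi)), sum(dichotomize(tifb, ne, r_lo)))
  }
  expect_error(dichotomization_rule(offset = 0.1,
                                    offset_grid = c(-0.04, 0.04)),
               "must contain")
})

test_that("without confounding the propensity scores collapse to the arm fraction", {
  co <- generate_cohort(tiny_spec(n = 4000, confounded = FALSE, seed = 12))
  arms <- dichotomize(co$tifb, co$ne)
  p <- fit_propensity(co, arms, adjustment_default)
  expect_lt(max(abs(p$scores - mean(arms))), 0.06)
})

test_that("propensity coefficients recover the generating values within 3 SE", {
  spec <- default_synthetic_spec(n_patients = 4000)
  truth <- spec$confounding_coefs
  for (s in 1:5) {
    spec <- default_synthetic_spec(n_patients = 4000, seed = 100 + s)
    co <- generate_cohort(spec)
    arms <- dichotomize(co$tifb, co$ne)
    z <- as.data.frame(
      obsuplift:::standardize_covariates(as.data.frame(co), spec$covariate_spec))
    fit <- glm(arms ~ year + ckd_stage + heart_disease + hypertension,
               data = z, family = binomial)
    est <- coef(summary(fit))
    for (nm in names(truth)) {
      expect_lt(abs(est[nm, "Estimate"] - truth[[nm]]),
                3 * est[nm, "Std. Error"])
    }
  }
})

test_that("an unknown adjustment covariate is rejected by name", {
  co <- generate_cohort(tiny_spec(seed = 13))
  arms <- dichotomize(co$tifb, co$ne)
  expect_error(fit_propensity(co, arms, c("year", "nope")), "nope")
  expect_error(fit_propensity(co, arms, character(0)), "non-empty")
})

test_that("IPTW weights follow the closed form and are bounded below by 1", {
  expect_equal(iptw_weights(0.5, 1L), 2)
  expect_equal(iptw_weights(0.25, 1L), 4)
  expect_equal(iptw_weights(0.25, 0L), 4 / 3)
  co <- generate_cohort(tiny_spec(n = 1000, seed = 14))
  arms <- dichotomize(co$tifb, co$ne)
  w <- iptw_weights(fit_propensity(co, arms, adjustment_default), arms)
  expect_true(all(w >= 1))
  # each arm's weighted count estimates the full cohort size
  expect_lt(abs(sum(w[arms == 1]) - nrow(co)) / nrow(co), 0.25)
  expect_lt(abs(sum(w[arms == 0]) - nrow(co)) / nrow(co), 0.25)
})

test_that("weighting balances the adjustment covariates (SMD < 0.1)", {
  co <- generate_cohort(default_synthetic_spec(n_patients = 5000, seed = 15))
  arms <- dichotomize(co$tifb, co$ne)
  w <- iptw_weights(fit_propensity(co, arms, adjustment_default), arms)
  tab <- smd_table(co, arms, w, adjustment_default)
  expect_true(all(tab$smd_weighted < 0.1))
  expect_gt(max(tab$smd_unweighted), max(tab$smd_weighted))
})

test_that("super-population replication counts round half away from zero", {
  expect_equal(obsuplift:::replication_counts(1.23456, 10000), 12346)
  expect_equal(obsuplift:::replication_counts(1, 10000), 10000)
  expect_equal(obsuplift:::replication_counts(c(1.00005, 2.5), 10000),
               c(10001, 25000))
})

test_that("the sampled pseudo-population has 2n records, n per arm, all traceable", {
  co <- generate_cohort(tiny_spec(n = 500, seed = 16))
  arms <- dichotomize(co$tifb, co$ne)
  w <- iptw_weights(fit_propensity(co, arms, adjustment_default), arms)
  pp <- build_pseudo_population(co, arms, w, n_per_arm = 500, seed = 3)
  expect_equal(nrow(pp), 1000)
  expect_equal(as.vector(table(pp$arm)), c(500, 500))
  expect_true(all(pp$source_id %in% co$patient_id))
  expect_identical(pp, build_pseudo_population(co, arms, w, n_per_arm = 500, seed = 3))
  # sampled arms agree with the source patients' dichotomized arms
  expect_identical(pp$arm, arms[match(pp$source_id, co$patient_id)])
})

test_that("pseudo-population sampling balances confounders across arms", {
  co <- generate_cohort(default_synthetic_spec(n_patients = 2000, seed = 17))
  arms <- dichotomize(co$tifb, co$ne)
  w <- iptw_weights(fit_propensity(co, arms, adjustment_default), arms)
  pp <- build_pseudo_population(co, arms, w, n_per_arm = 5000, seed = 4)
  tab <- smd_table(pp, pp$arm, rep(1, nrow(pp)), adjustment_default)
  expect_true(all(tab$smd_unweighted < 0.1))
})

test_that("the ATE estimator is exact in degenerate cases and null under no effect", {
  co <- generate_cohort(tiny_spec(n = 2000, effect = "null",
                                  confounded = FALSE, seed = 18))
  arms <- dichotomize(co$tifb, co$ne)
  est <- estimate_ate(co, arms, adjustment_default, n_boot = 50, seed = 1)
  expect_lt(abs(est$ate), 0.05)
  expect_error(estimate_ate(co, arms, adjustment_default, n_boot = 1), "n_boot")
  co$outcome_beneficial <- rep(1L, nrow(co))
  est1 <- estimate_ate(co, arms, adjustment_default, n_boot = 10, seed = 1)
  expect_identical(est1$ate, 0)
})

test_that("without confounding, unadjusted and IPTW estimates agree", {
  co <- generate_cohort(tiny_spec(n = 5000, confounded = FALSE, seed = 19))
  arms <- dichotomize(co$tifb, co$ne)
  naive <- mean(co$outcome_beneficial[arms == 1]) -
    mean(co$outcome_beneficial[arms == 0])
  est <- estimate_ate(co, arms, adjustment_default, n_boot = 20, seed = 1)
  expect_lt(abs(est$ate - naive), 0.02)
})

test_that("confounding biases the naive contrast but not the IPTW estimator", {
  naive_bias <- iptw_bias <- numeric(0)
  for (s in 1:10) {
    co <- generate_cohort(default_synthetic_spec(n_patients = 5000, seed = 200 + s))
    arms <- dichotomize(co$tifb, co$ne)
    w <- iptw_weights(fit_propensity(co, arms, adjustment_default), arms)
    truth <- mean(co$true_uplift)
    naive_bias <- c(naive_bias,
                    mean(co$outcome_beneficial[arms == 1]) -
                      mean(co$outcome_beneficial[arms == 0]) - truth)
    iptw_bias <- c(iptw_bias,
                   obsuplift:::hajek_ate(co$outcome_beneficial, arms, w) - truth)
  }
  expect_gt(mean(naive_bias), 0.008)       # biased upward
  expect_lt(abs(mean(iptw_bias)), 0.008)   # debiased
  expect_gt(mean(naive_bias), abs(mean(iptw_bias)))
})
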