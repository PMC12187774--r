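small_config <- function(master_seed = 1, ...) {
  experiment_config(n_bootstrap = 3, n_pseudo_samples = 1, n_cv_splits = 2,
                    learners = list(
                      logistic = learner_spec("logistic_regression"),
                      random_forest = learner_spec("random_forest",
                                                   list(ntree = 50L))),
                    master_seed = master_seed, ...)
}

test_that("two runs with the same master seed are identical", {
  co <- generate_cohort(tiny_spec(n = 250, seed = 61))
  r1 <- run_experiment(co, small_config(master_seed = 5))
  r2 <- run_experiment(co, small_config(master_seed = 5))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$ate, r2$ate)
  r3 <- run_experiment(co, small_config(master_seed = 6))
  expect_false(identical(r1$replicates, r3$replicates))
})

test_that("replicate seeds are pure functions of the master seed", {
  s1 <- obsuplift:::derive_seed(7, 3, 2, 1)
  expect_identical(s1, obsuplift:::derive_seed(7, 3, 2, 1))
  expect_false(s1 == obsuplift:::derive_seed(7, 3, 2, 2))
  expect_false(s1 == obsuplift:::derive_seed(8, 3, 2, 1))
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("the report is self-consistent", {
  co <- generate_cohort(tiny_spec(n = 250, seed = 62))
  cfg <- small_config(master_seed = 9)
  r <- run_experiment(co, cfg)
  n_rep <- cfg$n_bootstrap * cfg$n_pseudo_samples * cfg$n_cv_splits
  aq <- r$summary[r$summary$metric == "auqc", ]
  expect_true(all(aq$n_replicates == n_rep))
  expect_true(all(aq$ci_low <= aq$mean & aq$mean <= aq$ci_high))
  # aggregated means equal the arithmetic mean of the per-replicate exports
  for (i in seq_len(nrow(aq))) {
    vals <- r$replicates$value[r$replicates$model == aq$model[i] &
                               r$replicates$metric == "auqc"]
    expect_equal(aq$mean[i], mean(vals))
  }
  expect_true(all(rowSums(r$response_types) - 1 < 1e-12))
})

test_that("grouped source-patient splitting is null-safe for every learner", {
  co <- generate_cohort(default_synthetic_spec(n_patients = 800,
                                               effect = "null", seed = 63))
  cfg <- experiment_config(n_bootstrap = 6, n_pseudo_samples = 2,
                           n_cv_splits = 2,
                           learners = list(
                             logistic = learner_spec("logistic_regression"),
                             random_forest = learner_spec("random_forest",
                                                          list(ntree = 80L))),
                           master_seed = 3, split_unit = "source_patient")
  r <- run_experiment(co, cfg)
  aq <- r$summary[r$summary$metric == "auqc", ]
  rand <- aq[aq$model == "random", ]
  for (m in setdiff(aq$model, c("random", "optimal"))) {
    row <- aq[aq$model == m, ]
    expect_true(row$ci_low <= rand$ci_high && rand$ci_low <= row$ci_high,
                label = paste("AUQC CI of", m, "overlaps the random benchmark"))
  }
})

test_that("scale_factor shrinks the replication counts", {
  cfg <- experiment_config(n_bootstrap = 500, n_pseudo_samples = 5,
                           scale_factor = 0.04)
  expect_equal(cfg$n_bootstrap, 20L)
  expect_equal(cfg$n_pseudo_samples, 1L)
})

test_that("the stratified cohort summary conserves counts", {
  co <- generate_cohort(tiny_spec(n = 500, seed = 64))
  tab <- summarize_cohort(co)
  sizes <- attr(tab, "group_sizes")
  expect_equal(sizes[["overall"]], 500)
  expect_equal(sizes[["beneficial"]] + sizes[["adverse"]], 500)
  # every covariate appears in the table
  expect_true(all(covariate_names(co) %in% tab$variable))
})

test_that("binary prevalences are summarized accurately at scale", {
  spec <- synthetic_spec(
    10000,
    list(flag = list(type = "binary", prevalence = 0.5)),
    outcome_coefs = c(flag = 0.2), base_rate_beneficial = 0.7, seed = 65)
  co <- generate_cohort(spec)
  tab <- summarize_cohort(co)
  cell <- tab$overall[tab$variable == "flag" & tab$level == "1"]
  pct <- as.numeric(sub(".*\\((.*)%\\)", "\\1", cell))
  expect_lt(abs(pct - 50), 2)
})

test_that("a single-record cohort summarizes to its own values", {
  co <- generate_cohort(tiny_spec(n = 2, seed = 66))[1, ]
  co <- as_cohort(as.data.frame(co),
                  covariate_names(generate_cohort(tiny_spec(n = 2, seed = 66))))
  tab <- summarize_cohort(co)
  row <- tab[tab$variable == "age", ]
  expect_match(row$overall, sprintf("^%.1f", co$age))
})

test_that("the treatment arm grows monotonically with the offset", {
  co <- generate_cohort(tiny_spec(n = 800, seed = 67))
  cfg <- small_config()
  res <- sensitivity_over_offsets(co, cfg, n_boot = 20)
  expect_equal(res$offset, cfg$rule$offset_grid)
  expect_true(all(diff(res$n_treat) >= 0))
  expect_true(all(res$n_treat + res$n_control == nrow(co)))
})

test_that("an offset below all data flags a degenerate empty arm", {
  co <- generate_cohort(tiny_spec(n = 300, seed = 68))
  cfg <- small_config(rule = dichotomization_rule(
    slope = 0.02, offset = -5, offset_grid = c(-5, -0.04)))
  res <- sensitivity_over_offsets(co, cfg, n_boot = 20)
  expect_true(res$degenerate[res$offset == -5])
  expect_equal(res$n_treat[res$offset == -5], 0)
})

test_that("a YAML configuration round-trips into the constructors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "treatment:",
    "  slope: 0.02",
    "  offset: -0.04",
    "  adjustment_set: [year, ckd_stage]",
    "learners:",
    "  logistic:",
    "    kind: logistic_regression",
    "experiment:",
    "  n_bootstrap: 4",
    "  n_pseudo_samples: 1",
    "  master_seed: 11"), path)
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg$config, "experiment_config")
  expect_equal(cfg$config$n_bootstrap, 4L)
  expect_equal(cfg$config$adjustment_set, c("year", "ckd_stage"))
  expect_equal(names(cfg$config$learners), "logistic")
  expect_null(cfg$spec)
})
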