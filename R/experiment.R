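#' Configuration of the nested bootstrap evaluation
#'
#' The full-study profile is 500 bootstrap resamples x 5 pseudo-population
#' samples x 2 cross-validation splits with a 60/40 train/evaluation split
#' and an IPTW weight multiplier of 10,000. The default desk-scale profile
#' (20 x 2 x 2) keeps the same structure at a size suited to interactive use;
#' `scale_factor` shrinks the bootstrap and pseudo-sample counts further.
#'
#' @param n_bootstrap Bootstrap resamples of the cohort.
#' @param n_pseudo_samples Pseudo-population draws per bootstrap.
#' @param n_cv_splits Cross-validation splits per pseudo-sample.
#' @param train_fraction Fraction of pseudo-population records used for model
#'   building (remainder for evaluation).
#' @param learners Named list of [learner_spec()]s; each is fit both as a
#'   two-model uplift learner and as a single baseline prediction model.
#' @param rule [dichotomization_rule()].
#' @param adjustment_set Propensity-model covariates (confounder set).
#' @param multiplier IPTW super-population weight multiplier.
#' @param clip_epsilon Propensity clipping bound.
#' @param master_seed Master seed; every replicate seed is a pure function of
#'   it and the replicate coordinates.
#' @param scale_factor In (0, 1]; multiplies `n_bootstrap` and
#'   `n_pseudo_samples` (ceiling, minimum 1) for scaled-down runs.
#' @param split_unit `"record"` (default) draws the cross-validation samples
#'   from the pseudo-population records, so copies of one original patient
#'   can fall on both sides of the split — this is the resampling scheme the
#'   evaluation design describes, and flexible learners can exploit the
#'   duplication; `"source_patient"` keeps all copies of an original patient
#'   on one side, giving a leakage-free evaluation.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_bootstrap = 20L,
                              n_pseudo_samples = 2L,
                              n_cv_splits = 2L,
                              train_fraction = 0.6,
                              learners = list(
                                logistic = learner_spec("logistic_regression"),
                                random_forest = learner_spec("random_forest")),
                              rule = dichotomization_rule(),
                              adjustment_set = c("year", "ckd_stage",
                                                 "heart_disease", "hypertension"),
                              multiplier = 10000,
                              clip_epsilon = 0.01,
                              master_seed = 1L,
                              scale_factor = 1,
                              split_unit = c("record", "source_patient")) {
  split_unit <- match.arg(split_unit)
  stopifnot(train_fraction > 0, train_fraction < 1,
            n_bootstrap >= 1, n_pseudo_samples >= 1, n_cv_splits >= 1,
            scale_factor > 0, scale_factor <= 1)
  structure(list(
    n_bootstrap = max(1L, as.integer(ceiling(n_bootstrap * scale_factor))),
    n_pseudo_samples = max(1L, as.integer(ceiling(n_pseudo_samples * scale_factor))),
    n_cv_splits = as.integer(n_cv_splits),
    train_fraction = train_fraction,
    learners = learners,
    rule = rule,
    adjustment_set = adjustment_set,
    multiplier = multiplier,
    clip_epsilon = clip_epsilon,
    master_seed = as.integer(master_seed),
    split_unit = split_unit),
    class = "experiment_config")
}

# pure function of the master seed and replicate coordinates; < 2^31
derive_seed <- function(master, b = 0L, s = 0L, c = 0L) {
  as.integer(((master %% 1000003) * 2237 + b * 104729 + s * 1299709 +
                c * 15485863) %% 2147483587L) + 1L
}

# stratified train/eval split of pseudo-population records by arm and outcome
# within arm; with unit = "source_patient", all copies of one original patient
# stay on the same side of the split
split_train_eval <- function(data, train_fraction, seed,
                             unit = c("record", "source_patient")) {
  unit <- match.arg(unit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  train <- logical(nrow(data))
  if (unit == "record") {
    strata <- interaction(data$arm, data$outcome_beneficial, drop = TRUE)
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      n_tr <- max(1L, round(length(idx) * train_fraction))
      train[sample(idx, n_tr)] <- TRUE
    }
  } else {
    gid <- if (!is.null(data$.origin)) data$.origin else data$source_id
    groups <- !duplicated(gid)
    ginfo <- data.frame(gid = gid[groups], arm = data$arm[groups],
                        y = data$outcome_beneficial[groups])
    strata <- interaction(ginfo$arm, ginfo$y, drop = TRUE)
    train_gid <- character(0)
    for (lev in levels(strata)) {
      g <- ginfo$gid[strata == lev]
      n_tr <- max(1L, round(length(g) * train_fraction))
      train_gid <- c(train_gid, as.character(sample(as.character(g), n_tr)))
    }
    train <- as.character(gid) %in% train_gid
  }
  list(train = which(train), eval = which(!train))
}

#' Run the full uplift evaluation experiment
#'
#' For each bootstrap resample of the cohort (with replacement, original
#' size): dichotomize, refit the propensity model and IPTW weights, then for
#' each pseudo-population sample (2n records, n per arm) and each
#' cross-validation split (stratified by arm and outcome): fit every
#' configured learner as a two-model uplift model and as a baseline
#' prediction model on the train fraction, and evaluate AUQC (model, random
#' and optimal benchmarks on the same evaluation records), per-arm AUROCs of
#' the uplift sub-models, baseline AUROC, and response-type frequencies on
#' the evaluation fraction. The ATE is estimated per bootstrap. Metrics are
#' aggregated as the mean with a percentile 95% interval across replicates.
#'
#' Replicates that fail (e.g. a single-class arm in a fold) are skipped and
#' counted; the run aborts if more than 5% fail.
#'
#' @param cohort An `uplift_cohort`.
#' @param config An [experiment_config()].
#' @return Object of class `evaluation_report`: `summary` (model, metric,
#'   mean, ci_low, ci_high, n_replicates), `replicates` (per-replicate
#'   records), `ate` (per-bootstrap estimates + summary), `response_types`
#'   (mean frequency per uplift model), `n_failed`, `failures`, `config`.
#' @export
run_experiment <- function(cohort, config) {
  stopifnot(inherits(cohort, "uplift_cohort"), inherits(config, "experiment_config"))
  n <- nrow(cohort)
  feats <- covariate_names(cohort)
  ms <- config$master_seed
  reps <- list(); rt_list <- list(); ate_b <- numeric(0)
  failures <- list()
  n_total <- 0L

  for (b in seq_len(config$n_bootstrap)) {
    seed_b <- derive_seed(ms, b)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed_b)
    idx <- sample.int(n, n, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    boot <- cohort[idx, , drop = FALSE]
    boot$.origin <- cohort$patient_id[idx]
    boot$patient_id <- seq_len(n)
    boot <- as_cohort(as.data.frame(boot), feats)
    arms <- dichotomize(boot$tifb, boot$ne, config$rule)

    stage <- tryCatch({
      prop <- fit_propensity(boot, arms, config$adjustment_set, config$clip_epsilon)
      w <- iptw_weights(prop, arms)
      ate_b <- c(ate_b, hajek_ate(boot$outcome_beneficial, arms, w))
      list(prop = prop, w = w)
    }, error = function(e) e)
    if (inherits(stage, "error")) {
      n_total <- n_total + config$n_pseudo_samples * config$n_cv_splits
      failures[[length(failures) + 1L]] <-
        list(b = b, s = NA, c = NA, message = conditionMessage(stage))
      next
    }

    for (s in seq_len(config$n_pseudo_samples)) {
      seed_s <- derive_seed(ms, b, s)
      pp <- build_pseudo_population(boot, arms, stage$w, n_per_arm = n,
                                    multiplier = config$multiplier,
                                    seed = seed_s)
      for (cv in seq_len(config$n_cv_splits)) {
        n_total <- n_total + 1L
        seed_c <- derive_seed(ms, b, s, cv)
        res <- tryCatch(
          evaluate_replicate(pp, feats, config, seed_c),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            list(b = b, s = s, c = cv, message = conditionMessage(res))
          next
        }
        res$metrics$b <- b; res$metrics$s <- s; res$metrics$c <- cv
        reps[[length(reps) + 1L]] <- res$metrics
        rt_list[[length(rt_list) + 1L]] <- res$response_types
      }
    }
  }

  if (length(failures) > 0.05 * n_total) {
    stop("more than 5% of replicates failed (", length(failures), "/", n_total,
         "); first error: ", failures[[1]]$message)
  }
  replicates <- do.call(rbind, reps)
  agg <- do.call(rbind, lapply(
    split(replicates, list(replicates$model, replicates$metric), drop = TRUE),
    function(d) data.frame(
      model = d$model[1], metric = d$metric[1], mean = mean(d$value),
      ci_low = stats::quantile(d$value, 0.025, names = FALSE),
      ci_high = stats::quantile(d$value, 0.975, names = FALSE),
      n_replicates = nrow(d))))
  rownames(agg) <- NULL
  rt <- Reduce(`+`, rt_list) / length(rt_list)
  ate_summary <- data.frame(
    mean = mean(ate_b),
    ci_low = stats::quantile(ate_b, 0.025, names = FALSE),
    ci_high = stats::quantile(ate_b, 0.975, names = FALSE),
    n_bootstrap = length(ate_b))
  structure(list(summary = agg, replicates = replicates,
                 ate = list(per_bootstrap = ate_b, summary = ate_summary),
                 response_types = rt,
                 n_failed = length(failures), n_replicates = n_total,
                 failures = failures, config = config),
            class = "evaluation_report")
}

# one (bootstrap, pseudo-sample, cv-split) replicate: fit + evaluate
evaluate_replicate <- function(pp, feats, config, seed) {
  sp <- split_train_eval(pp, config$train_fraction, seed,
                         unit = config$split_unit %||% "record")
  train <- pp[sp$train, , drop = FALSE]
  eval_ <- pp[sp$eval, , drop = FALSE]
  if (length(unique(eval_$arm)) < 2L) stop("evaluation fold has a single arm")

  rows <- list(); rts <- list()
  y <- eval_$outcome_beneficial; a <- eval_$arm
  for (ln in names(config$learners)) {
    lspec <- config$learners[[ln]]
    lspec$seed <- seed
    um <- fit_two_model(train, lspec, feats)
    sc <- predict_uplift(um, eval_)
    q <- qini_curve(sc$uplift, a, y, tie_seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste0("uplift_", ln), metric = "auqc", value = auqc(q))
    if (length(unique(y[a == 1])) == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = paste0("uplift_", ln), metric = "auroc_treatment",
        value = auroc(y[a == 1], sc$p_treat[a == 1]))
    }
    if (length(unique(y[a == 0])) == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = paste0("uplift_", ln), metric = "auroc_control",
        value = auroc(y[a == 0], sc$p_control[a == 0]))
    }
    rt <- table(classify_response_type(sc$p_treat, sc$p_control))
    rts[[paste0("uplift_", ln)]] <- as.numeric(rt) / sum(rt)

    bm <- fit_baseline_prediction(train, lspec, feats)
    pr <- predict_outcome_prob(bm, eval_)
    qb <- qini_curve(pr, a, y, tie_seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste0("prediction_", ln), metric = "auqc", value = auqc(qb))
    if (length(unique(y)) == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = paste0("prediction_", ln), metric = "auroc", value = auroc(y, pr))
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(seed, 7L))
  rand_scores <- stats::runif(nrow(eval_))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rows[[length(rows) + 1L]] <- data.frame(
    model = "random", metric = "auqc",
    value = auqc(qini_curve(rand_scores, a, y, ties = "stable")))
  rows[[length(rows) + 1L]] <- data.frame(
    model = "optimal", metric = "auqc",
    value = optimal_benchmark_auqc(a, y))

  rt_mat <- do.call(rbind, rts)
  colnames(rt_mat) <- levels(classify_response_type(0.6, 0.6))
  list(metrics = do.call(rbind, rows), response_types = rt_mat)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Uplift evaluation report:",
      x$n_replicates, "replicates (", x$n_failed, "failed )\n")
  cat(sprintf("  ATE (IPTW, Hajek): %.3f [%.3f, %.3f]\n",
              x$ate$summary$mean, x$ate$summary$ci_low, x$ate$summary$ci_high))
  aq <- x$summary[x$summary$metric == "auqc", ]
  for (i in seq_len(nrow(aq))) {
    cat(sprintf("  AUQC %-22s %.3f [%.3f, %.3f]\n", aq$model[i],
                aq$mean[i], aq$ci_low[i], aq$ci_high[i]))
  }
  invisible(x)
}

#' Stratified cohort summary table
#'
#' Table-1-style summary stratified by the beneficial outcome: categorical
#' covariates (0/1 or few integer levels) as counts and percentages, other
#' numerics as median \[IQR\].
#'
#' @param cohort An `uplift_cohort`.
#' @param max_levels Maximum distinct integer values still summarized as
#'   categorical.
#' @return Data frame: `variable`, `level`, `overall`, `beneficial`,
#'   `adverse` (formatted strings), plus group sizes as attributes.
#' @export
summarize_cohort <- function(cohort, max_levels = 6L) {
  y <- cohort$outcome_beneficial
  groups <- list(overall = rep(TRUE, nrow(cohort)),
                 beneficial = y == 1, adverse = y == 0)
  fmt_median <- function(v) sprintf("%.1f [%.1f;%.1f]", stats::median(v),
                                    stats::quantile(v, 0.25),
                                    stats::quantile(v, 0.75))
  fmt_count <- function(v, lev) {
    k <- sum(v == lev)
    sprintf("%d (%.1f%%)", k, if (length(v)) 100 * k / length(v) else 0)
  }
  rows <- list()
  for (nm in c(covariate_names(cohort), "tifb", "ne")) {
    v <- cohort[[nm]]
    levs <- sort(unique(v))
    categorical <- all(v == round(v)) && length(levs) <= max_levels
    if (categorical) {
      for (lev in levs) {
        cells <- vapply(groups, function(g) fmt_count(v[g], lev), character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = as.character(lev),
          overall = cells[["overall"]], beneficial = cells[["beneficial"]],
          adverse = cells[["adverse"]])
      }
    } else {
      cells <- vapply(groups, function(g)
        if (any(g)) fmt_median(v[g]) else "", character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "median [IQR]",
        overall = cells[["overall"]], beneficial = cells[["beneficial"]],
        adverse = cells[["adverse"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- c(overall = nrow(cohort),
                                beneficial = sum(y == 1), adverse = sum(y == 0))
  out
}

#' Sensitivity of arm sizes and the ATE to the dichotomization offset
#'
#' Repeats dichotomization, propensity estimation and the IPTW ATE for every
#' offset in the rule's grid. Offsets producing an empty arm are reported
#' with `degenerate = TRUE` rather than failing.
#'
#' @param cohort An `uplift_cohort`.
#' @param config An [experiment_config()] (supplies the rule's offset grid,
#'   the adjustment set and the clipping bound).
#' @param n_boot Bootstrap replicates for each offset's ATE interval.
#' @return Data frame: `offset`, `n_control`, `n_treat`, `ate`, `ci_low`,
#'   `ci_high`, `degenerate`.
#' @export
sensitivity_over_offsets <- function(cohort, config, n_boot = 100L) {
  grid <- config$rule$offset_grid
  res <- lapply(grid, function(off) {
    rule <- dichotomization_rule(config$rule$slope, off, offset_grid = off)
    arms <- dichotomize(cohort$tifb, cohort$ne, rule)
    if (length(unique(arms)) < 2L) {
      return(data.frame(offset = off, n_control = sum(arms == 0),
                        n_treat = sum(arms == 1), ate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        degenerate = TRUE))
    }
    est <- tryCatch(
      estimate_ate(cohort, arms, config$adjustment_set, n_boot = n_boot,
                   seed = derive_seed(config$master_seed,
                                      round(1000 * (off + 1))),
                   clip_epsilon = config$clip_epsilon),
      error = function(e) NULL)
    if (is.null(est)) {
      return(data.frame(offset = off, n_control = sum(arms == 0),
                        n_treat = sum(arms == 1), ate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        degenerate = TRUE))
    }
    data.frame(offset = off, n_control = sum(arms == 0),
               n_treat = sum(arms == 1), ate = est$ate,
               ci_low = est$ci_low, ci_high = est$ci_high, degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Read an experiment configuration from a YAML file
#'
#' Expects top-level blocks `synthetic`, `treatment`, `learners` and
#' `experiment`; every field is optional and falls back to the corresponding
#' constructor default.
#'
#' @param path YAML file path.
#' @return List with elements `spec` (a [synthetic_spec()], or `NULL` if no
#'   `synthetic` block) and `config` (an [experiment_config()]).
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rule <- do.call(dichotomization_rule, cfg$treatment[
    intersect(names(cfg$treatment), c("slope", "offset", "offset_grid"))] %||% list())
  learners <- if (is.null(cfg$learners)) {
    list(logistic = learner_spec("logistic_regression"),
         random_forest = learner_spec("random_forest"))
  } else {
    lapply(cfg$learners, function(l) {
      learner_spec(l$kind, l$hyperparameters %||% list(), l$seed %||% 1L)
    })
  }
  exp_args <- cfg$experiment %||% list()
  exp_args$learners <- learners
  exp_args$rule <- rule
  if (!is.null(cfg$treatment$adjustment_set)) {
    exp_args$adjustment_set <- cfg$treatment$adjustment_set
  }
  if (!is.null(cfg$treatment$multiplier)) exp_args$multiplier <- cfg$treatment$multiplier
  if (!is.null(cfg$treatment$clip_epsilon)) exp_args$clip_epsilon <- cfg$treatment$clip_epsilon
  config <- do.call(experiment_config, exp_args)
  spec <- NULL
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    for (f in c("confounding_coefs", "outcome_coefs", "effect_coefs")) {
      if (!is.null(syn[[f]])) syn[[f]] <- unlist(syn[[f]])
    }
    spec <- do.call(synthetic_spec, syn)
  }
  list(spec = spec, config = config)
}
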