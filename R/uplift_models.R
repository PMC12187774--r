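#' Outcome learner specification
#'
#' @param kind `"logistic_regression"` (ridge-penalized logistic model; the
#'   light L2 penalty keeps fits stable under the quasi-separation that
#'   resampled pseudo-populations can produce) or `"random_forest"`
#'   (probability = out-of-bag-free vote fraction).
#' @param hyperparameters Named list. Logistic: `lambda` (default 1e-3).
#'   Random forest: `ntree` (default 500), `mtry` (default floor(sqrt(p))),
#'   `nodesize` (default 1, i.e. fully grown trees).
#' @param seed Integer seed used for every stochastic fit.
#' @return Object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("logistic_regression", "random_forest"),
                         hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    logistic_regression = list(lambda = 1e-3),
    random_forest = list(ntree = 500L, mtry = NULL, nodesize = 1L))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "learner_spec")
}

# fit a probability learner for a binary outcome; returns an object usable
# with predict_prob()
fit_learner <- function(data, outcome, feature_names, spec, label = "data") {
  y <- data[[outcome]]
  if (length(unique(y)) < 2L) {
    stop("cannot fit outcome model on ", label, ": outcome has a single class")
  }
  unknown <- setdiff(feature_names, names(data))
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  x <- data[, feature_names, drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    logistic_regression = {
      xm <- as.matrix(x)
      if (ncol(xm) < 2L) {
        # glmnet needs >= 2 columns; plain ML fit is fine for one feature
        df <- data.frame(.y = y, x)
        list(kind = "glm",
             fit = suppressWarnings(stats::glm(.y ~ ., data = df,
                                               family = stats::binomial())))
      } else {
        list(kind = "glmnet",
             fit = suppressWarnings(
               glmnet::glmnet(xm, factor(y, levels = c(0, 1)),
                              family = "binomial", alpha = 0,
                              lambda = spec$hyperparameters$lambda,
                              standardize = TRUE)),
             lambda = spec$hyperparameters$lambda)
      }
    },
    random_forest = {
      hp <- spec$hyperparameters
      mtry <- if (is.null(hp$mtry)) max(1L, floor(sqrt(ncol(x)))) else hp$mtry
      list(kind = "rf",
           fit = randomForest::randomForest(
             x = x, y = factor(y, levels = c(0, 1)),
             ntree = hp$ntree, mtry = mtry, nodesize = hp$nodesize))
    })
  structure(list(engine = fit, feature_names = feature_names, spec = spec),
            class = "outcome_learner")
}

# probability of outcome 1 on new data
predict_prob <- function(learner, newdata) {
  unknown <- setdiff(learner$feature_names, names(newdata))
  if (length(unknown)) {
    stop("newdata lacks feature(s): ", paste(unknown, collapse = ", "))
  }
  x <- newdata[, learner$feature_names, drop = FALSE]
  eng <- learner$engine
  p <- switch(eng$kind,
    glm = stats::predict(eng$fit, newdata = x, type = "response"),
    glmnet = as.numeric(stats::predict(eng$fit, newx = as.matrix(x),
                                       s = eng$lambda, type = "response")),
    rf = stats::predict(eng$fit, newdata = x, type = "prob")[, "1"])
  as.numeric(p)
}

#' Fit a two-model (T-learner) uplift model
#'
#' Fits one outcome-probability learner on the treatment-arm records and an
#' independent one on the control-arm records of a pseudo-population (or any
#' data frame carrying `arm` and `outcome_beneficial`). The per-patient
#' uplift is the difference of their predictions.
#'
#' @param data A `pseudo_population` (or data frame) with columns `arm`,
#'   `outcome_beneficial` and the features.
#' @param spec A [learner_spec()].
#' @param feature_names Features available to the learners (typically all
#'   cohort covariates, not only the causal adjustment set).
#' @return Object of class `uplift_model`.
#' @export
fit_two_model <- function(data, spec, feature_names) {
  stopifnot(all(c("arm", "outcome_beneficial") %in% names(data)))
  dt <- data[data$arm == 1L, , drop = FALSE]
  dc <- data[data$arm == 0L, , drop = FALSE]
  if (!nrow(dt) || !nrow(dc)) stop("both arms must be non-empty")
  model_treatment <- fit_learner(dt, "outcome_beneficial", feature_names, spec,
                                 label = "treatment arm")
  model_control <- fit_learner(dc, "outcome_beneficial", feature_names, spec,
                               label = "control arm")
  structure(list(model_treatment = model_treatment,
                 model_control = model_control,
                 learner_spec = spec,
                 feature_names = feature_names),
            class = "uplift_model")
}

#' Predict per-patient uplift
#'
#' @param model An [fit_two_model()] result.
#' @param newdata Data frame with the model's features.
#' @return Data frame: `p_treat`, `p_control`, `uplift = p_treat - p_control`
#'   (in `[-1, 1]`).
#' @export
predict_uplift <- function(model, newdata) {
  stopifnot(inherits(model, "uplift_model"))
  p_treat <- predict_prob(model$model_treatment, newdata)
  p_control <- predict_prob(model$model_control, newdata)
  data.frame(p_treat = p_treat, p_control = p_control,
             uplift = p_treat - p_control)
}

#' Classify response types from the two arm-specific probabilities
#'
#' Each probability is dichotomized at `threshold` (strictly above counts as
#' a likely beneficial outcome): benefits either way = Sure Thing, neither
#' way = Lost Cause, only under treatment = Persuadable, only under control =
#' Do-not-disturb.
#'
#' @param p_treat,p_control Probabilities of the beneficial outcome under the
#'   treatment and control regime.
#' @param threshold Dichotomization threshold in (0, 1).
#' @return Factor with levels `SureThing`, `LostCause`, `Persuadable`,
#'   `DoNotDisturb`.
#' @export
classify_response_type <- function(p_treat, p_control, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  stopifnot(all(p_treat >= 0 & p_treat <= 1), all(p_control >= 0 & p_control <= 1))
  t1 <- p_treat > threshold
  c1 <- p_control > threshold
  out <- ifelse(t1 & c1, "SureThing",
         ifelse(!t1 & !c1, "LostCause",
         ifelse(t1 & !c1, "Persuadable", "DoNotDisturb")))
  factor(out, levels = c("SureThing", "LostCause", "Persuadable", "DoNotDisturb"))
}

#' Fit a traditional (single) outcome prediction model
#'
#' One probability learner fit on all records of both arms pooled; the arm
#' indicator is deliberately NOT a feature, so the model sorts patients purely
#' by predicted beneficial-outcome likelihood (baseline risk), providing the
#' benchmark against which uplift-based sorting is compared.
#'
#' @inheritParams fit_two_model
#' @return Object of class `baseline_model`.
#' @export
fit_baseline_prediction <- function(data, spec, feature_names) {
  stopifnot("outcome_beneficial" %in% names(data))
  learner <- fit_learner(data, "outcome_beneficial", feature_names, spec,
                         label = "pooled arms")
  structure(list(learner = learner, learner_spec = spec,
                 feature_names = feature_names),
            class = "baseline_model")
}

#' Predicted beneficial-outcome probability of a baseline model
#'
#' @param model A [fit_baseline_prediction()] result.
#' @param newdata Data frame with the model's features.
#' @return Numeric probability vector.
#' @export
predict_outcome_prob <- function(model, newdata) {
  stopifnot(inherits(model, "baseline_model"))
  predict_prob(model$learner, newdata)
}
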