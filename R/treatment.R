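#' Dichotomization rule for the joint fluid-norepinephrine exposure
#'
#' A line in the (TIFB, NE) plane with fixed slope splits the cohort into a
#' treatment arm (high total intraoperative fluid balance / low
#' norepinephrine, strictly below the line) and a control arm (on or above
#' the line). The offset grid supports sensitivity analyses over alternative
#' dichotomization choices.
#'
#' @param slope Line slope, ug/kg/min per mL/kg/h.
#' @param offset Line intercept in NE units, ug/kg/min (primary choice -0.04).
#' @param offset_grid Strictly increasing offsets for sensitivity analysis;
#'   must contain `offset`.
#' @return Object of class `dichotomization_rule`.
#' @export
dichotomization_rule <- function(slope = 0.02, offset = -0.04,
                                 offset_grid = seq(-0.12, 0.08, by = 0.04)) {
  stopifnot(is.finite(slope), is.finite(offset),
            all(is.finite(offset_grid)), !is.unsorted(offset_grid, strictly = TRUE))
  if (!any(abs(offset_grid - offset) < 1e-12)) {
    stop("`offset_grid` must contain `offset`")
  }
  structure(list(slope = slope, offset = offset, offset_grid = offset_grid),
            class = "dichotomization_rule")
}

#' Dichotomize the (TIFB, NE) exposure into two arms
#'
#' @param tifb Total intraoperative fluid balance, mL/kg/h.
#' @param ne Norepinephrine rate, ug/kg/min.
#' @param rule A [dichotomization_rule()].
#' @return Integer vector: 1 (treatment, high TIFB / low NE) iff
#'   `ne < offset + slope * tifb`; 0 otherwise. Points exactly on the line go
#'   to control.
#' @export
dichotomize <- function(tifb, ne, rule = dichotomization_rule()) {
  stopifnot(inherits(rule, "dichotomization_rule"),
            length(tifb) == length(ne))
  if (any(!is.finite(tifb)) || any(!is.finite(ne))) {
    stop("`tifb` and `ne` must be finite")
  }
  as.integer(ne < rule$offset + rule$slope * tifb)
}

#' Propensity scores for the dichotomized regime
#'
#' Main-effects logistic regression of the arm indicator on the adjustment
#' covariates; fitted probabilities are clipped to `[clip_epsilon,
#' 1 - clip_epsilon]` so downstream inverse-probability weights are finite.
#'
#' @param cohort An `uplift_cohort`.
#' @param arms 0/1 arm per patient (see [dichotomize()]).
#' @param adjustment_set Covariate names entering the propensity model (the
#'   confounder set identified, e.g., by a backdoor analysis; supplied as
#'   configuration, not computed).
#' @param clip_epsilon Score clipping bound.
#' @return Object of class `propensity_result`: `scores`, `adjustment_set`,
#'   `coefficients`, `overlap_summary` (per-arm score quantiles and the shared
#'   support interval).
#' @export
fit_propensity <- function(cohort, arms, adjustment_set, clip_epsilon = 0.01) {
  stopifnot(length(arms) == nrow(cohort), all(arms %in% c(0L, 1L)))
  if (!length(adjustment_set)) stop("`adjustment_set` must be non-empty")
  if (length(unique(arms)) < 2L) stop("both arms must be non-empty")
  unknown <- setdiff(adjustment_set, covariate_names(cohort))
  if (length(unknown)) {
    stop("adjustment covariate(s) not in cohort: ", paste(unknown, collapse = ", "))
  }
  dat <- as.data.frame(cohort)[, adjustment_set, drop = FALSE]
  dat$.arm <- arms
  fit <- suppressWarnings(
    stats::glm(.arm ~ ., data = dat, family = stats::binomial()))
  raw <- stats::fitted(fit)
  if (max(abs(stats::coef(fit)[-1]), na.rm = TRUE) > 50 ||
      all(raw[arms == 1] > 1 - 1e-8) && all(raw[arms == 0] < 1e-8)) {
    stop("propensity model separates the arms perfectly; widen `clip_epsilon` ",
         "or use a smaller `adjustment_set`")
  }
  scores <- pmin(pmax(raw, clip_epsilon), 1 - clip_epsilon)
  qs <- function(a) stats::quantile(scores[arms == a], c(0, 0.25, 0.5, 0.75, 1))
  overlap <- list(
    control = qs(0L), treatment = qs(1L),
    shared_support = c(max(min(scores[arms == 0]), min(scores[arms == 1])),
                       min(max(scores[arms == 0]), max(scores[arms == 1]))))
  structure(list(scores = as.numeric(scores),
                 adjustment_set = adjustment_set,
                 coefficients = stats::coef(fit),
                 clip_epsilon = clip_epsilon,
                 overlap_summary = overlap),
            class = "propensity_result")
}

#' Inverse probability of treatment weights
#'
#' `w_i = arm_i / score_i + (1 - arm_i) / (1 - score_i)`. With clipped scores
#' all weights are finite and >= 1; a patient with score 0.5 has weight 2.
#'
#' @param propensity A [fit_propensity()] result (or a numeric score vector).
#' @param arms 0/1 arm per patient.
#' @return Numeric weight vector.
#' @export
iptw_weights <- function(propensity, arms) {
  scores <- if (inherits(propensity, "propensity_result")) propensity$scores else propensity
  stopifnot(length(scores) == length(arms), all(scores > 0 & scores < 1))
  arms / scores + (1 - arms) / (1 - scores)
}

# deterministic, platform-stable: round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# integer replication counts of the IPTW super-population
replication_counts <- function(weights, multiplier) {
  round_half_away(weights * multiplier)
}

#' Sample a confounder-balanced pseudo-population
#'
#' Conceptually each patient is replicated `round(weight * multiplier)` times
#' (half away from zero) into a super-population; `n_per_arm` records are then
#' drawn uniformly with replacement from each arm's super-population. The draw
#' is implemented as weighted sampling with probabilities proportional to the
#' integer replication counts, which is distributionally identical and does
#' not materialize the super-population.
#'
#' @param cohort An `uplift_cohort`.
#' @param arms 0/1 arm per patient.
#' @param weights IPTW weights (see [iptw_weights()]).
#' @param n_per_arm Number of records drawn per arm (the paper-style default
#'   is the original cohort size, giving a pseudo-population of size 2n).
#' @param multiplier Weight multiplier used to build integer replication
#'   counts.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A data frame of class `pseudo_population` with the cohort columns
#'   plus `arm` and `source_id`; provenance (multiplier, seed, source size) in
#'   attributes.
#' @export
build_pseudo_population <- function(cohort, arms, weights,
                                    n_per_arm = nrow(cohort),
                                    multiplier = 10000, seed = 1L) {
  stopifnot(n_per_arm >= 1, multiplier >= 1,
            length(arms) == nrow(cohort), length(weights) == nrow(cohort))
  counts <- replication_counts(weights, multiplier)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  idx <- integer(0)
  for (a in c(0L, 1L)) {
    ia <- which(arms == a)
    if (!length(ia) || sum(counts[ia]) == 0) {
      stop("arm ", a, " has zero total replication count")
    }
    idx <- c(idx, sample(ia, n_per_arm, replace = TRUE, prob = counts[ia]))
  }
  out <- as.data.frame(cohort)[idx, , drop = FALSE]
  out$arm <- arms[idx]
  out$source_id <- cohort$patient_id[idx]
  rownames(out) <- NULL
  structure(out,
            covariate_names = covariate_names(cohort),
            provenance = list(multiplier = multiplier, seed = seed,
                              n_source = nrow(cohort), n_per_arm = n_per_arm),
            class = c("pseudo_population", "data.frame"))
}

# Hajek (per-arm normalized) weighted difference in mean outcomes
hajek_ate <- function(y, arms, weights) {
  sum(weights * y * arms) / sum(weights * arms) -
    sum(weights * y * (1 - arms)) / sum(weights * (1 - arms))
}

#' IPTW estimate of the average treatment effect
#'
#' Point estimate by the Hajek (per-arm weight-normalized) estimator of the
#' difference in beneficial-outcome probability, treatment minus control;
#' percentile-bootstrap 95% CI over patients with the propensity model refit
#' in every replicate.
#'
#' @param cohort An `uplift_cohort`.
#' @param arms 0/1 arm per patient.
#' @param adjustment_set Propensity covariates.
#' @param n_boot Bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param clip_epsilon Propensity clipping bound.
#' @param weights Optional precomputed weights for the point estimate;
#'   bootstrap replicates always refit.
#' @return List: `ate`, `ci_low`, `ci_high`, `n_boot_used`.
#' @export
estimate_ate <- function(cohort, arms, adjustment_set, n_boot = 200L,
                         seed = 1L, clip_epsilon = 0.01, weights = NULL) {
  stopifnot(length(unique(arms)) == 2L)
  if (n_boot < 2) stop("`n_boot` must be >= 2")
  if (is.null(weights)) {
    weights <- iptw_weights(fit_propensity(cohort, arms, adjustment_set,
                                           clip_epsilon), arms)
  }
  y <- cohort$outcome_beneficial
  ate <- hajek_ate(y, arms, weights)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- nrow(cohort)
  boots <- rep(NA_real_, n_boot)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    a <- arms[idx]
    if (length(unique(a)) < 2L) next
    w <- tryCatch(
      iptw_weights(fit_propensity(cohort[idx, , drop = FALSE], a,
                                  adjustment_set, clip_epsilon), a),
      error = function(e) NULL)
    if (is.null(w)) next
    boots[r] <- hajek_ate(y[idx], a, w)
  }
  boots <- boots[!is.na(boots)]
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  list(ate = ate, ci_low = ci[1], ci_high = ci[2], n_boot_used = length(boots))
}

#' Standardized mean differences before and after weighting
#'
#' Balance diagnostic for the adjustment covariates: the absolute difference
#' in (weighted) means between arms divided by the pooled unweighted standard
#' deviation.
#'
#' @param cohort An `uplift_cohort`.
#' @param arms 0/1 arm per patient.
#' @param weights IPTW weights.
#' @param covariates Covariate names to tabulate (default: all).
#' @return Data frame: `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
smd_table <- function(cohort, arms, weights, covariates = covariate_names(cohort)) {
  wmean <- function(v, w) sum(v * w) / sum(w)
  res <- lapply(covariates, function(nm) {
    v <- cohort[[nm]]
    s_pool <- sqrt((stats::var(v[arms == 1]) + stats::var(v[arms == 0])) / 2)
    if (!is.finite(s_pool) || s_pool == 0) s_pool <- 1
    data.frame(
      covariate = nm,
      smd_unweighted = abs(mean(v[arms == 1]) - mean(v[arms == 0])) / s_pool,
      smd_weighted = abs(wmean(v[arms == 1], weights[arms == 1]) -
                         wmean(v[arms == 0], weights[arms == 0])) / s_pool)
  })
  do.call(rbind, res)
}
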