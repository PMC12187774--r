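#' Specification of a synthetic observational cohort
#'
#' Describes the data-generating process for a synthetic cystectomy-style
#' cohort: patient covariates, a confounded latent regime assignment, an
#' inversely coupled pair of continuous exposures (total intraoperative fluid
#' balance, TIFB, in mL/kg/h, and norepinephrine rate, NE, in ug/kg/min), and
#' a binary beneficial outcome (1 = no postoperative acute kidney injury) with
#' a known heterogeneous treatment effect.
#'
#' Coefficients in `confounding_coefs`, `outcome_coefs` and `effect_coefs`
#' apply to internally standardized covariates (continuous: centered and
#' scaled by the declared mean/sd; binary: centered at the declared
#' prevalence; ordinal: centered at the implied mean). Each may contain an
#' `"(Intercept)"` entry.
#'
#' @param n_patients Number of patients (>= 2).
#' @param covariate_spec Named list; each element is a list with `type`
#'   (`"continuous"`, `"binary"` or `"ordinal"`) and parameters: `mean`/`sd`
#'   for continuous, `prevalence` for binary, `probs` (and optional `values`)
#'   for ordinal.
#' @param confounding_coefs Named numeric: log-odds coefficients of covariates
#'   on the latent probability of the treatment regime (high TIFB / low NE).
#' @param outcome_coefs Named numeric: coefficients on the baseline (control)
#'   log-odds of the beneficial outcome.
#' @param effect_coefs Named numeric: coefficients on the treatment-interaction
#'   log-odds; drives heterogeneity of the conditional average treatment effect.
#' @param base_rate_beneficial Target marginal probability of the beneficial
#'   outcome, strictly inside (0, 1).
#' @param tifb_ne_coupling Slope of NE on TIFB in the latent exposure model
#'   (ug/kg/min per mL/kg/h); negative for the inverse fluid-vasopressor
#'   relationship.
#' @param noise_sd Standard deviation of the Gaussian NE noise (ug/kg/min).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param rule [dichotomization_rule()] used to place regime-leaning patients
#'   on their side of the (TIFB, NE) plane.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients,
                           covariate_spec,
                           confounding_coefs = numeric(),
                           outcome_coefs = numeric(),
                           effect_coefs = numeric(),
                           base_rate_beneficial = 0.783,
                           tifb_ne_coupling = -0.02,
                           noise_sd = 0.02,
                           seed = 1L,
                           rule = dichotomization_rule()) {
  stopifnot(is.numeric(n_patients), length(n_patients) == 1L, n_patients >= 2)
  if (!is.list(covariate_spec) || is.null(names(covariate_spec)) ||
      any(names(covariate_spec) == "")) {
    stop("`covariate_spec` must be a fully named list")
  }
  if (!(base_rate_beneficial > 0 && base_rate_beneficial < 1)) {
    stop("`base_rate_beneficial` must lie strictly inside (0, 1)")
  }
  for (cf in list(confounding_coefs, outcome_coefs, effect_coefs)) {
    if (length(cf)) {
      if (any(!is.finite(cf))) stop("coefficients must be finite")
      bad <- setdiff(names(cf), c(names(covariate_spec), "(Intercept)"))
      if (length(bad)) stop("coefficient refers to unknown covariate: ", bad[1])
    }
  }
  shared <- intersect(setdiff(names(confounding_coefs), "(Intercept)"),
                      setdiff(names(outcome_coefs), "(Intercept)"))
  conf_active <- any(confounding_coefs[setdiff(names(confounding_coefs), "(Intercept)")] != 0)
  if (conf_active && !length(shared)) {
    stop("at least one covariate must appear in both `confounding_coefs` and ",
         "`outcome_coefs`; otherwise regime assignment is not confounded")
  }
  stopifnot(is.numeric(tifb_ne_coupling), length(tifb_ne_coupling) == 1L,
            noise_sd > 0)
  structure(
    list(n_patients = as.integer(n_patients),
         covariate_spec = covariate_spec,
         confounding_coefs = confounding_coefs,
         outcome_coefs = outcome_coefs,
         effect_coefs = effect_coefs,
         base_rate_beneficial = base_rate_beneficial,
         tifb_ne_coupling = tifb_ne_coupling,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         rule = rule),
    class = "synthetic_spec")
}

#' Default synthetic cohort specification
#'
#' A checked-in fixture at the scale of a single-center cystectomy database:
#' 1,482 patients, ~78.3% beneficial-outcome rate, an inverse TIFB-NE
#' relationship, regime assignment confounded by calendar year (the practice
#' shift toward restrictive fluids with pre-emptive norepinephrine), chronic
#' kidney disease stage, heart disease and hypertension, and a heterogeneous
#' positive treatment effect averaging about 0.12 on the probability scale.
#'
#' @param n_patients Cohort size.
#' @param base_rate_beneficial Target marginal beneficial-outcome rate.
#' @param effect `"heterogeneous"` (default fixture), `"null"` (zero treatment
#'   effect everywhere) or `"homogeneous"` (constant positive effect).
#' @param confounded If `FALSE`, zero out the confounding coefficients (regime
#'   assignment independent of covariates).
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
default_synthetic_spec <- function(n_patients = 1482L,
                                   base_rate_beneficial = 0.783,
                                   effect = c("heterogeneous", "null", "homogeneous"),
                                   confounded = TRUE,
                                   seed = 1L) {
  effect <- match.arg(effect)
  covs <- list(
    age            = list(type = "continuous", mean = 68.5, sd = 10.5),
    bmi            = list(type = "continuous", mean = 25.8, sd = 4.3),
    asa            = list(type = "ordinal", probs = c(0.021, 0.494, 0.460, 0.025)),
    ckd_stage      = list(type = "ordinal", probs = c(0.284, 0.410, 0.260, 0.036, 0.010)),
    copd           = list(type = "binary", prevalence = 0.201),
    heart_disease  = list(type = "binary", prevalence = 0.312),
    hypertension   = list(type = "binary", prevalence = 0.510),
    statins        = list(type = "binary", prevalence = 0.233),
    neoadj_chemo   = list(type = "binary", prevalence = 0.155),
    year           = list(type = "continuous", mean = 2010.5, sd = 5.5)
  )
  confound <- if (confounded) {
    c("(Intercept)" = -0.28, year = -1.10, ckd_stage = 0.25,
      heart_disease = -0.35, hypertension = -0.30)
  } else {
    c("(Intercept)" = -0.28)
  }
  outc <- c(age = -0.25, bmi = -0.30, asa = -0.25, ckd_stage = -0.30,
            heart_disease = -0.30, hypertension = -0.45, statins = -0.20,
            year = -0.15)
  eff <- switch(effect,
    heterogeneous = c("(Intercept)" = 0.72, hypertension = 0.45,
                      heart_disease = 0.40, age = 0.30, ckd_stage = 0.25),
    homogeneous   = c("(Intercept)" = 0.72),
    null          = numeric())
  synthetic_spec(
    n_patients = n_patients,
    covariate_spec = covs,
    confounding_coefs = confound,
    outcome_coefs = outc,
    effect_coefs = eff,
    base_rate_beneficial = base_rate_beneficial,
    tifb_ne_coupling = -0.02,
    noise_sd = 0.02,
    seed = seed)
}

# standardized design matrix implied by a covariate_spec
standardize_covariates <- function(x, covariate_spec) {
  z <- matrix(0, nrow(x), length(covariate_spec),
              dimnames = list(NULL, names(covariate_spec)))
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    v <- x[[nm]]
    z[, nm] <- switch(cs$type,
      continuous = (v - cs$mean) / cs$sd,
      binary = v - cs$prevalence,
      ordinal = {
        vals <- if (is.null(cs$values)) seq_along(cs$probs) else cs$values
        v - sum(vals * cs$probs)
      },
      stop("unknown covariate type: ", cs$type))
  }
  z
}

linpred <- function(z, coefs) {
  eta <- rep(0, nrow(z))
  if (!length(coefs)) return(eta)
  if ("(Intercept)" %in% names(coefs)) eta <- eta + coefs[["(Intercept)"]]
  slope_names <- setdiff(names(coefs), "(Intercept)")
  if (length(slope_names)) eta <- eta + as.vector(z[, slope_names, drop = FALSE] %*% coefs[slope_names])
  eta
}

# intercept calibration: find alpha with mean(arm*plogis(eta1) + (1-arm)*plogis(eta0))
# = target, by bisection; eta0 = alpha + off, eta1 = alpha + off + tau
calibrate_alpha <- function(off, tau, arm, target, tol = 0.005) {
  marg <- function(a) mean(arm * stats::plogis(a + off + tau) +
                           (1 - arm) * stats::plogis(a + off))
  lo <- -20; hi <- 20
  if (marg(lo) > target || marg(hi) < target) {
    stop("intercept calibration failed: target beneficial rate unreachable")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (marg(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  alpha <- (lo + hi) / 2
  if (abs(marg(alpha) - target) > 0.02) {
    stop("intercept calibration missed the target marginal rate by > 0.02")
  }
  if (abs(marg(alpha) - target) > tol) {
    warning("intercept calibration tolerance ", tol, " not met exactly")
  }
  alpha
}

#' Generate a synthetic observational cohort
#'
#' Draws covariates, assigns each patient a latent hemodynamic regime with
#' probability `plogis(confounding_coefs . z)`, places the continuous
#' exposures (TIFB, NE) on the corresponding side of the primary
#' dichotomization line, and draws both potential outcomes from logistic
#' models with a calibrated intercept, so that the marginal beneficial rate
#' matches `base_rate_beneficial`. The observed outcome is the potential
#' outcome of the realized arm (consistency), and the ground-truth per-patient
#' uplift `plogis(eta + tau) - plogis(eta)` is stored alongside.
#'
#' @param spec A [synthetic_spec()].
#' @return A cohort data frame of class `uplift_cohort` with columns
#'   `patient_id`, the covariates, `tifb`, `ne`, `outcome_beneficial`,
#'   `po_y0`, `po_y1`, `true_uplift`; covariate names are kept in
#'   `attr(, "covariate_names")`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_patients
  covs <- spec$covariate_spec
  x <- data.frame(row.names = seq_len(n))
  for (nm in names(covs)) {
    cs <- covs[[nm]]
    x[[nm]] <- switch(cs$type,
      continuous = stats::rnorm(n, cs$mean, cs$sd),
      binary = stats::rbinom(n, 1L, cs$prevalence),
      ordinal = {
        vals <- if (is.null(cs$values)) seq_along(cs$probs) else cs$values
        sample(vals, n, replace = TRUE, prob = cs$probs)
      })
  }
  z <- standardize_covariates(x, covs)

  # latent regime assignment (1 = high TIFB / low NE)
  prop <- stats::plogis(linpred(z, spec$confounding_coefs))
  arm <- stats::rbinom(n, 1L, prop)

  rule <- spec$rule
  # smallest TIFB at which a nonnegative NE can still fall below the line
  tifb_floor <- if (rule$slope > 0) max(0, -rule$offset / rule$slope) else 0
  tifb <- numeric(n); ne <- numeric(n)
  conf_shift <- 0.005 * (x$heart_disease %||% 0) + 0.005 * (x$hypertension %||% 0)
  if (length(conf_shift) == 1L) conf_shift <- rep(conf_shift, n)

  i1 <- which(arm == 1L); i0 <- which(arm == 0L)
  if (length(i1)) {
    tifb[i1] <- tifb_floor + stats::rlnorm(length(i1), log(3.0), 0.55)
    thr <- rule$offset + rule$slope * tifb[i1]
    ne1 <- pmax(0, stats::rnorm(length(i1), 0.002 + conf_shift[i1] * 0.2, spec$noise_sd / 2))
    over <- ne1 >= thr
    if (any(over)) ne1[over] <- stats::runif(sum(over), 0, thr[over]) * 0.9
    ne[i1] <- ne1
  }
  if (length(i0)) {
    tifb[i0] <- stats::rlnorm(length(i0), log(1.74), 0.55)
    thr <- rule$offset + rule$slope * tifb[i0]
    ne0 <- 0.085 + spec$tifb_ne_coupling * tifb[i0] + conf_shift[i0] +
      stats::rnorm(length(i0), 0, spec$noise_sd)
    ne[i0] <- pmax(ne0, pmax(thr, 0) + 1e-9, 0)
  }
  stopifnot(all(dichotomize(tifb, ne, rule) == arm))

  # potential outcomes with calibrated intercept
  off <- linpred(z, spec$outcome_coefs)
  tau <- linpred(z, spec$effect_coefs)
  alpha <- calibrate_alpha(off, tau, arm, spec$base_rate_beneficial)
  p0 <- stats::plogis(alpha + off)
  p1 <- stats::plogis(alpha + off + tau)
  po_y0 <- stats::rbinom(n, 1L, p0)
  po_y1 <- stats::rbinom(n, 1L, p1)

  out <- cbind(
    data.frame(patient_id = seq_len(n)),
    x,
    data.frame(tifb = tifb, ne = ne,
               outcome_beneficial = ifelse(arm == 1L, po_y1, po_y0),
               po_y0 = po_y0, po_y1 = po_y1,
               true_uplift = p1 - p0))
  as_cohort(out, covariate_names = names(covs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct / validate a cohort object
#'
#' @param df Data frame with at least `patient_id`, the covariates, `tifb`,
#'   `ne` and `outcome_beneficial`.
#' @param covariate_names Ordered covariate column names.
#' @return `df` with class `uplift_cohort` and a `covariate_names` attribute.
#' @export
as_cohort <- function(df, covariate_names) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  needed <- c("patient_id", covariate_names, "tifb", "ne", "outcome_beneficial")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("`patient_id` must be unique")
  if (any(df$ne < 0)) stop("`ne` must be nonnegative")
  if (!all(df$outcome_beneficial %in% c(0L, 1L))) {
    stop("`outcome_beneficial` must be 0/1 (1 = beneficial = no PO-AKI)")
  }
  attr(df, "covariate_names") <- covariate_names
  class(df) <- unique(c("uplift_cohort", class(df)))
  df
}

#' @export
print.uplift_cohort <- function(x, ...) {
  cat("Observational uplift cohort:", nrow(x), "patients,",
      length(covariate_names(x)), "covariates\n")
  cat("  beneficial outcome rate:",
      sprintf("%.1f%%", 100 * mean(x$outcome_beneficial)), "\n")
  if ("true_uplift" %in% names(x)) {
    cat("  synthetic ground truth: mean uplift",
        sprintf("%.3f", mean(x$true_uplift)), "\n")
  }
  invisible(x)
}

#' Covariate names of a cohort
#' @param cohort An `uplift_cohort`.
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(cohort) attr(cohort, "covariate_names")

#' Write / read a cohort CSV
#'
#' The on-disk format is a plain comma-separated file with a header row,
#' '.' decimal separator and empty strings for missing fields. `read_cohort`
#' performs complete-case filtering: rows with any missing field are dropped
#' and the number of dropped rows is reported via a message and stored in
#' `attr(, "n_dropped")`.
#'
#' @param cohort An `uplift_cohort`.
#' @param path File path.
#' @return `read_cohort` returns an `uplift_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @param covariate_names Optional explicit covariate names; by default every
#'   column other than `patient_id`, the exposures, the outcome and the
#'   synthetic ground-truth columns is treated as a covariate.
#' @export
read_cohort <- function(path, covariate_names = NULL) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  mandatory <- c("tifb", "ne", "outcome_beneficial")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop("cohort file lacks mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!"patient_id" %in% names(df)) df$patient_id <- seq_len(nrow(df))
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  rownames(df) <- NULL
  if (n_dropped > 0) {
    message("read_cohort: dropped ", n_dropped,
            " incomplete row(s) (complete-case analysis)")
  }
  if (is.null(covariate_names)) {
    covariate_names <- setdiff(
      names(df),
      c("patient_id", "tifb", "ne", "outcome_beneficial",
        "po_y0", "po_y1", "true_uplift"))
  }
  out <- as_cohort(df, covariate_names)
  attr(out, "n_dropped") <- n_dropped
  out
}
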