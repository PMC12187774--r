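---
title: "Uplift modeling of hemodynamic regimes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uplift modeling of hemodynamic regimes: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

After major surgery roughly one patient in five develops acute kidney
injury (PO-AKI). Risk prediction models say *who* is at risk; they do not
say *which* intraoperative hemodynamic strategy — liberal fluids with little
vasopressor, or restrictive fluids supported by norepinephrine — would have
given a particular patient the better chance of an AKI-free recovery.
`obsuplift` implements the prescriptive alternative: per-patient **uplift**
(the conditional average treatment effect),

$$u(x) = P(Y = 1 \mid T = 1, x) - P(Y = 1 \mid T = 0, x),$$

with $Y = 1$ the *beneficial* outcome (no PO-AKI; this coding is used in
every function and file format, and the CSV column is named
`outcome_beneficial` to prevent silent inversion) and $T = 1$ the high
total-intraoperative-fluid-balance (TIFB) / low norepinephrine (NE) regime.

# From a joint continuous exposure to two arms

The exposure is the pair (TIFB in mL·kg⁻¹·h⁻¹, NE in µg·kg⁻¹·min⁻¹), which
is inversely related in practice: restrictive-fluid protocols lean on
pre-emptive norepinephrine. `dichotomize()` splits the plane by the line
$\mathrm{NE} = \beta_0 + 0.02\,\mathrm{TIFB}$, treatment being strictly
below it. The slope is fixed; the offset $\beta_0$ defaults to −0.04 with a
sensitivity grid −0.12 … 0.08 in steps of 0.04
(`sensitivity_over_offsets()`). Two small conventions we fixed:

* **Boundary points go to control.** "High TIFB / low NE" reads as strict
  dominance; the boundary has measure zero for continuous exposures, so the
  choice cannot move results, but it must be deterministic.
* Raising the offset can only grow the treatment arm (monotonicity); the
  test suite checks this as a property.

# Confounding, IPTW and the pseudo-population

Arms are not exchangeable in observational data — most visibly here through
the calendar-year practice shift (restrictive fluid management was adopted
around 2007, so later years are predominantly control). The adjustment set
is **supplied as configuration** (default: year, chronic-kidney-disease
stage, heart disease, hypertension); deriving it from a causal graph is out
of scope. `fit_propensity()` is a main-effects logistic regression of the
arm on those covariates, with ordinal covariates entered as integers.
Fitted scores are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 0.01$: this guarantees finite weights without a weight
truncation scheme, and overlap should additionally be inspected via the
`overlap_summary` and the exported standardized-mean-difference table
(`smd_table()`; the weighted SMDs of the adjustment set fall below 0.1 on
the default synthetic cohort).

`build_pseudo_population()` follows the weight-replication construction:
each patient conceptually enters a super-population
$\mathrm{round}(w_i \times 10{,}000)$ times (rounding half away from zero —
deterministic and platform-stable), and $n$ records per arm are drawn
uniformly **with replacement**, giving a balanced pseudo-population of size
$2n$. We sample with replacement because the super-population is itself a
replication device and without-replacement draws could be infeasible for
arms dominated by a few heavy weights. The draw is implemented as weighted
sampling with probabilities proportional to the integer counts, which is
distributionally identical and avoids materializing ~15 million rows.

The average treatment effect uses the **Hájek (per-arm normalized)**
estimator — bounded in $[-1, 1]$ and standard for weighted proportions —
with a percentile bootstrap over patients in which the propensity model is
refit in every replicate.

# Two-model uplift and the baseline comparison

`fit_two_model()` fits one outcome-probability learner per arm and predicts
uplift as the difference. Learners:

* **Logistic regression** with a light ridge penalty (λ = 10⁻³ via glmnet).
  Resampled pseudo-populations regularly produce quasi-separated folds; the
  penalty keeps the fit defined while leaving probabilities essentially
  unpenalized at these sample sizes. Coefficients are never the target.
* **Random forest** with conventional defaults: 500 trees, √p feature
  subsampling, fully grown trees, probability = vote fraction.

All cohort covariates are available to the outcome learners — not only the
causal adjustment set. The **baseline prediction model**
(`fit_baseline_prediction()`) pools both arms and deliberately excludes the
arm indicator, so it sorts patients purely by predicted baseline risk; that
is the clinically familiar strategy the uplift models are compared against.
Response types are derived by thresholding both arm probabilities at 0.5
(strictly above = likely beneficial): benefits either way *Sure Thing*,
neither *Lost Cause*, only under treatment *Persuadable*, only under
control *Do-not-disturb*.

# Qini evaluation

Because individual uplift is never observed, evaluation is aggregate.
`qini_curve()` sorts patients by descending score and computes, per head
fraction $p$, $q(p) = Y_T(p) - Y_C(p)\,N_T(p)/N_C(p)$. Numerical choices:

* **Normalization.** $q$ is divided by the total number of treated patients
  $N_T$, making the AUQC dimensionless and comparable across sample sizes;
  any fixed constant leaves cross-model comparisons on identical data
  unchanged.
* **Grid.** $p = 0.01, \dots, 1.00$; the trapezoidal integration error at
  this density is far below reporting precision.
* **Ties** are broken by a seeded uniform jitter drawn once per evaluation
  (explicit and reproducible), or stably by input order for deterministic
  block orderings.
* **Control-free heads.** For small $p$ the head may contain no controls;
  the control term is then set to 0, the only finite continuous completion
  of the formula. A consequence worth knowing: in degenerate all-beneficial
  data a treated-first ordering still yields a positive AUQC even though
  $q(1) = 0$.

Two benchmarks frame every model's AUQC. The **random benchmark** averages
the AUQC of uniformly random orderings (its expectation is the straight
line to $q_{norm}(1)$, i.e. AUQC $\approx q_{norm}(1)/2$). The **optimal
benchmark** orders observable proxies of the response types: treated
successes first, then control failures, then treated failures, finally
control successes. We place treated successes strictly before control
failures because that refinement attains the maximum AUQC over *all*
permutations (verified against exhaustive search at small n); interleaving
the two groups dilutes the early head and is suboptimal. An alternative
reading — all beneficial outcomes first regardless of arm — is available
via `mode = "beneficial_first"`.

`uplift_by_decile()` reports observed uplift per predicted-uplift decile
(decile 1 = top 10%); deciles where an arm is empty are flagged `NA`, never
zero, and degenerate (e.g. constant) scores collapse into the top bin.
`auroc()` is the Mann–Whitney rank statistic with midrank tie handling, and
`proportion_ci_wald()` the normal-approximation interval used for
descriptive incidences.

# The nested bootstrap and a note on splitting

`run_experiment()` nests: bootstrap resample of the cohort (propensity and
weights refit per resample) → pseudo-population draws → stratified 60/40
train/evaluation splits; metrics are aggregated as means with percentile
2.5/97.5 intervals **across all replicates** (aggregating across
bootstrap-level means instead is a one-line change we decided against, as
the flat pool is the simpler estimand). Every replicate seed is a pure
function of the master seed and the (bootstrap, sample, split) coordinates,
so runs are exactly reproducible and replicates are independent of
execution order. CV splits are stratified by arm and by outcome within arm,
preventing single-class arms in evaluation folds; replicates that still
fail are skipped and counted, and the run aborts beyond 5% failures.

One design point deserves emphasis. The cross-validation samples are drawn
from the **pseudo-population records** (`split_unit = "record"`, the
default, mirroring the evaluation design this workflow implements). Because
the pseudo-population contains many copies of each source patient, copies
routinely land on both sides of the split, and a fully grown random forest
can partially memorize them — which raises its apparent AUROC (≈ 0.98) and
uplift AUQC relative to the ridge-logistic learner. This record-level
resampling is therefore part of what the reported metrics *mean*: they
measure sorting performance within the weighted resampling scheme, not
transportable out-of-sample discrimination. Setting
`split_unit = "source_patient"` keeps all copies of a source patient on one
side; under that leakage-free splitting all models collapse onto the random
benchmark when the true treatment effect is null (a property the test suite
checks), and flexible learners lose their resampling advantage. Users
comparing learner families should look at both.

# The synthetic cohort generator

No clinical data ships with the package; `generate_cohort()` +
`default_synthetic_spec()` emulate the statistical structure the analysis
assumes, with a known ground truth:

* **Covariates** match published marginal summaries of a single-center
  cystectomy cohort (age ≈ 68.5 ± 10.5, BMI ≈ 25.8 ± 4.3, ASA and CKD-stage
  category frequencies, comorbidity prevalences, year of procedure).
  Only marginals are targeted — the real joint distribution is unknown — so
  passing tests demonstrate correctness of the *machinery*, not fidelity to
  any real covariance structure.
* **Regime assignment** is a latent Bernoulli with logistic propensity on
  standardized covariates; year carries the dominant (negative) coefficient,
  encoding the 2007 practice shift. Setting the confounding coefficients to
  zero makes the arms exchangeable.
* **Exposures**: TIFB is log-normal conditional on the arm (treatment
  median ≈ 5.0, control ≈ 1.7 mL·kg⁻¹·h⁻¹, mimicking skewed IQRs), and NE
  is a truncated-at-zero linear function of TIFB with negative coupling
  (−0.02), a small confounder shift and Gaussian noise — reproducing the
  many zero-NE patients in the treatment arm. Draws are then constrained to
  the latent regime's side of the primary dichotomization line, so the
  realized arm equals the latent assignment (consistency holds by
  construction).
* **Outcomes**: both potential outcomes are Bernoulli with logistic means
  $\alpha + \beta^\top z$ and $\alpha + \beta^\top z + \tau(z)$,
  $\tau(z) = \gamma^\top z$. The intercept $\alpha$ is calibrated by
  bisection so the marginal beneficial rate hits its target (tolerance
  0.005; a miss beyond 0.02 is an error). The default heterogeneous effect
  averages ≈ 0.12 on the probability scale, with hypertension, heart
  disease, age and CKD stage driving the heterogeneity; `effect = "null"`
  and `"homogeneous"` variants support null-safety and sensitivity checks.
* Everything is bit-reproducible given the spec seed, and the generator
  stores `po_y0`, `po_y1` and `true_uplift` so estimators can be scored
  against truth.

What the generator deliberately does **not** model: intraoperative time
courses and sequential fluid decisions (hence no treatment–confounder
feedback), KDIGO staging from creatinine trajectories, missing-data
mechanisms beyond complete-case reading, and treatment-related harms.

# Problem sizes and defaults

The package's own test and example runs use desk-scale sizes chosen to keep
Monte-Carlo error well below the effects being checked: cohorts of
600–10,000 for property checks, 100 seeds for interval-coverage studies,
and the 20 × 2 × 2 evaluation profile (80 replicates) for pipeline-level
comparisons; the full 500 × 5 × 2 study profile is a configuration change
(`n_bootstrap = 500, n_pseudo_samples = 5`), not a code change.

# Known limitations

The two-model estimator is the simplest uplift learner; X-/R-/DR-learners
and calibration post-processing are out of scope. The Qini estimator is the
plain one (no variance reduction). The Wald interval is used for
descriptive proportions because it matches the conventional reporting of
such cohorts, though it degrades near 0/1. The record-level splitting
caveat above applies to any flexible learner evaluated inside resampled
pseudo-populations.
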