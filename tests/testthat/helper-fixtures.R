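# Worked 8-patient evaluation fixture. Sorted by descending score the
# sequence of (arm, outcome) is fixed; the half-cohort head holds treated
# outcomes {1,1} and control outcomes {0,1}; totals are Y_T = 3, Y_C = 2,
# N_T = N_C = 4.
eight_patient_fixture <- function() {
  data.frame(
    score = 8:1,
    arm = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
    y   = c(1L, 0L, 1L, 1L, 0L, 1L, 1L, 0L))
}

# Independent brute-force evaluation of the incremental-uplift formula:
# for each quantile take the first ceiling(p * n) patients of an explicit
# ordering and apply q(p) = Y_T - Y_C * N_T / N_C directly (control term 0
# for a control-free head). Kept loop-based and separate from the package's
# cumulative-sum implementation.
bf_qini <- function(ord, arms, y, grid) {
  n <- length(ord)
  sapply(grid, function(p) {
    head_idx <- ord[seq_len(min(n, ceiling(p * n)))]
    yt <- sum(y[head_idx][arms[head_idx] == 1])
    yc <- sum(y[head_idx][arms[head_idx] == 0])
    nt <- sum(arms[head_idx] == 1)
    nc <- sum(arms[head_idx] == 0)
    if (nc == 0) yt else yt - yc * nt / nc
  })
}

bf_auqc <- function(ord, arms, y, grid) {
  qn <- bf_qini(ord, arms, y, grid) / sum(arms == 1)
  x <- c(0, grid); v <- c(0, qn)
  sum(diff(x) * (head(v, -1) + tail(v, -1)) / 2)
}

# all permutations of a vector (exhaustive search helper, n <= 8)
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# small synthetic specification used across module tests
tiny_spec <- function(n = 400, effect = "heterogeneous", confounded = TRUE,
                      seed = 1L) {
  default_synthetic_spec(n_patients = n, effect = effect,
                         confounded = confounded, seed = seed)
}

adjustment_default <- c("year", "ckd_stage", "heart_disease", "hypertension")

fast_learners <- function(ntree = 100L) {
  list(logistic = learner_spec("logistic_regression"),
       random_forest = learner_spec("random_forest", list(ntree = ntree)))
}
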