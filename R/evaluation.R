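#' Qini curve of a patient sorting
#'
#' Patients are sorted by descending score (ties broken by a seeded uniform
#' draw, or stably by input order). For each quantile `p` of the grid, the
#' head holds the first `ceiling(p * N)` patients and the incremental uplift
#' is
#' `q_raw(p) = Y_T(p) - Y_C(p) * N_T(p) / N_C(p)`,
#' where `Y` are sums of beneficial outcomes and `N` arm counts inside the
#' head; a head with no controls contributes a control term of 0 (the only
#' finite continuous completion at small `p`). `q_norm = q_raw / N_T` with
#' `N_T` the total number of treated patients, so the curve is dimensionless
#' and bounded in `[-1, 1]`.
#'
#' @param scores Sorting scores (predicted uplift, or predicted risk for a
#'   baseline model).
#' @param arms 0/1 arm per patient.
#' @param outcomes 0/1 beneficial outcome per patient.
#' @param grid Quantiles in (0, 1], sorted; default 0.01..1 by 0.01.
#' @param tie_seed Seed for the tie-breaking jitter.
#' @param ties `"random"` (seeded) or `"stable"` (input order).
#' @return Object of class `qini_curve`: data frame `p`, `q_raw`, `q_norm`
#'   with attributes `n`, `n_treated`.
#' @export
qini_curve <- function(scores, arms, outcomes, grid = seq(0.01, 1, by = 0.01),
                       tie_seed = 1L, ties = c("random", "stable")) {
  ties <- match.arg(ties)
  n <- length(scores)
  stopifnot(length(arms) == n, length(outcomes) == n,
            all(arms %in% c(0, 1)), all(outcomes %in% c(0, 1)))
  if (length(unique(arms)) < 2L) stop("both arms must be present")
  if (any(grid <= 0 | grid > 1) || is.unsorted(grid)) {
    stop("`grid` must be sorted and inside (0, 1]")
  }
  tb <- if (ties == "random") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(tie_seed)
    stats::runif(n)
  } else {
    seq_len(n)
  }
  ord <- order(-scores, tb)
  y <- outcomes[ord]; a <- arms[ord]
  cum_yt <- cumsum(y * a)
  cum_yc <- cumsum(y * (1 - a))
  cum_nt <- cumsum(a)
  cum_nc <- cumsum(1 - a)
  k <- pmin(n, ceiling(grid * n))
  ctrl_term <- ifelse(cum_nc[k] == 0, 0, cum_yc[k] * cum_nt[k] / cum_nc[k])
  q_raw <- cum_yt[k] - ctrl_term
  n_treated <- sum(arms)
  out <- data.frame(p = grid, q_raw = q_raw, q_norm = q_raw / n_treated)
  attr(out, "n") <- n
  attr(out, "n_treated") <- n_treated
  class(out) <- c("qini_curve", "data.frame")
  out
}

#' Area under the Qini curve
#'
#' Trapezoidal integral of the normalized Qini curve over the quantile grid,
#' prepending the origin (0, 0).
#'
#' @param curve A [qini_curve()].
#' @return Scalar AUQC.
#' @export
auqc <- function(curve) {
  stopifnot(inherits(curve, "qini_curve"), nrow(curve) >= 2L)
  x <- c(0, curve$p)
  y <- c(0, curve$q_norm)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' AUQC of random patient sorting
#'
#' Monte-Carlo benchmark: the AUQC obtained when patients are sorted by
#' independent uniform scores, averaged over `n_reps` orderings with a
#' percentile 95% interval. In expectation the random Qini curve is the
#' straight line to `q_norm(1)`, so the mean approaches `q_norm(1) / 2`.
#'
#' @param arms,outcomes As in [qini_curve()].
#' @param n_reps Number of random orderings.
#' @param seed Integer seed.
#' @param grid Quantile grid.
#' @return List: `mean`, `ci` (2.5/97.5 percentiles), `values`.
#' @export
random_benchmark_auqc <- function(arms, outcomes, n_reps = 1000L, seed = 1L,
                                  grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(n_reps >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- length(arms)
  vals <- vapply(seq_len(n_reps), function(i) {
    auqc(qini_curve(stats::runif(n), arms, outcomes, grid = grid, ties = "stable"))
  }, numeric(1))
  list(mean = mean(vals),
       ci = stats::quantile(vals, c(0.025, 0.975), names = FALSE),
       values = vals)
}

#' AUQC of an idealized optimal sorting
#'
#' Upper benchmark built from the observable proxy of the response types.
#' With mode `"observable_types"` (default) the ordering is: treated patients
#' with a beneficial outcome, then controls with an adverse outcome (both
#' consistent with the Persuadable type), then treated with an adverse
#' outcome, finally controls with a beneficial outcome; within a block the
#' input order is kept. Treated successes are placed strictly first because
#' that ordering attains the maximum AUQC achievable by any permutation.
#' Mode `"beneficial_first"` instead places all patients with a beneficial
#' outcome first, regardless of arm.
#'
#' @param arms,outcomes As in [qini_curve()].
#' @param grid Quantile grid.
#' @param mode Ordering convention (see above).
#' @return Scalar AUQC of the idealized ordering.
#' @export
optimal_benchmark_auqc <- function(arms, outcomes, grid = seq(0.01, 1, by = 0.01),
                                   mode = c("observable_types", "beneficial_first")) {
  mode <- match.arg(mode)
  if (length(unique(arms)) < 2L) stop("both arms must be present")
  block <- switch(mode,
    observable_types = ifelse(arms == 1 & outcomes == 1, 4,
                       ifelse(arms == 0 & outcomes == 0, 3,
                       ifelse(arms == 1 & outcomes == 0, 2, 1))),
    beneficial_first = ifelse(outcomes == 1, 2, 1))
  auqc(qini_curve(block, arms, outcomes, grid = grid, ties = "stable"))
}

#' Observed uplift by predicted-uplift decile
#'
#' Bins patients into deciles of the pooled score distribution (decile 1 =
#' top 0-10% of predicted uplift) and reports, per decile, the mean
#' beneficial-outcome rate in each arm and their difference (the observed
#' uplift). Deciles in which an arm is empty are flagged with `NA`, not zero;
#' when the score distribution is degenerate (e.g. constant scores) merged
#' deciles collapse into the topmost bin and the remaining rows are empty.
#'
#' @param scores,arms,outcomes As in [qini_curve()].
#' @return Data frame with 10 rows: `decile`, `n_treat`, `n_control`,
#'   `mean_treat`, `mean_control`, `uplift`.
#' @export
uplift_by_decile <- function(scores, arms, outcomes) {
  n <- length(scores)
  stopifnot(length(arms) == n, length(outcomes) == n)
  if (length(unique(arms)) < 2L) stop("both arms must be present")
  qs <- stats::quantile(scores, seq(0, 1, by = 0.1), names = FALSE)
  br <- unique(qs)
  if (length(br) < 2L) {
    decile <- rep(1L, n)
  } else {
    cutidx <- cut(scores, br, include.lowest = TRUE, labels = FALSE)
    # map each cut bin to its from-the-top decile via the upper edge's
    # position in the decile quantile sequence
    upper_pos <- vapply(seq_len(length(br) - 1L),
                        function(j) max(which(abs(qs - br[j + 1]) < .Machine$double.eps^0.5)),
                        integer(1))
    decile <- (12L - upper_pos)[cutidx]
  }
  res <- lapply(1:10, function(d) {
    sel <- decile == d
    nt <- sum(sel & arms == 1); nc <- sum(sel & arms == 0)
    mt <- if (nt > 0) mean(outcomes[sel & arms == 1]) else NA_real_
    mc <- if (nc > 0) mean(outcomes[sel & arms == 0]) else NA_real_
    data.frame(decile = d, n_treat = nt, n_control = nc,
               mean_treat = mt, mean_control = mc, uplift = mt - mc)
  })
  do.call(rbind, res)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Rank statistic of the scores of beneficial-outcome patients against the
#' rest; tied scores contribute one half via midranks.
#'
#' @param outcomes 0/1 outcome per patient (both classes required).
#' @param scores Numeric scores.
#' @return Scalar AUROC in `[0, 1]`.
#' @export
auroc <- function(outcomes, scores) {
  stopifnot(length(outcomes) == length(scores), all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wald confidence interval for a proportion
#'
#' `p = k / n` with the normal-approximation 95% interval
#' `p -/+ 1.96 * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`.
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Sample size (>= 1).
#' @return List: `p`, `lo`, `hi`.
#' @export
proportion_ci_wald <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  list(p = p, lo = max(0, p - half), hi = min(1, p + half))
}
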