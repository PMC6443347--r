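# Subject-level permutation inference on learning-rate differences.
#
# The resampling unit is always the whole subject: a subject's block series
# moves between groups (or between day labels) as one piece, preserving the
# within-subject correlation structure under the null.

# Internal representation: a list with the common block vector `x` and a
# (subjects x blocks) matrix `Y` of skill scores, rows named by subject.
as_series <- function(data, what = "group") {
  need <- c("subject", "block", "skill")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("block-series table is missing column(s): ",
         paste(missing, collapse = ", "))
  blocks <- sort(unique(as.numeric(data$block)))
  split_rows <- split(data, data$subject)
  Y <- t(vapply(split_rows, function(d) {
    if (nrow(d) != length(blocks) ||
        !identical(sort(as.numeric(d$block)), blocks))
      stop("each subject needs one observation for every block ",
           "(incomplete series for subject ", d$subject[1], ")")
    as.numeric(d$skill[order(d$block)])
  }, numeric(length(blocks))))
  list(x = blocks, Y = Y)
}

# Pooled slope of a set of subject series (rows of Y) on the block vector x.
pooled_slope <- function(x, Y, estimator, psi, tuning, tol, max_iter) {
  n <- nrow(Y)
  if (estimator == "ols") {
    xc <- x - mean(x)
    # pooled OLS slope is the mean of per-subject cross-products over Sxx
    sum(Y %*% xc) / (n * sum(xc * xc))
  } else {
    irls_core(rep(x, each = n), as.numeric(Y), psi, tuning, tol,
              max_iter)$coefficients[[2]]
  }
}

count_extreme <- function(null, obs, alternative) {
  switch(alternative,
         two_sided = sum(abs(null) >= abs(obs)),
         greater   = sum(null >= obs),
         less      = sum(null <= obs))
}

#' Permutation test for a group difference in learning rate
#'
#' Tests whether two groups differ in learning rate (the slope of the
#' pooled robust regression of skill on block, [fit_learning()]). Under the
#' null hypothesis of no group difference, subjects are randomly reassigned
#' to two groups of the original sizes, the slope difference is recomputed
#' for each reassignment, and the p-value is the proportion of resampled
#' differences at least as extreme as the observed one (ties count as
#' exceeding). With `exhaustive = TRUE` every distinct reassignment is
#' enumerated and the p-value is exact.
#'
#' @param groupA,groupB Block-series tables (columns `subject`, `block`,
#'   `skill`) for the two groups; every subject must have a complete block
#'   series and both groups must share the same blocks. At least 2 subjects
#'   per group.
#' @param n_perm Number of Monte-Carlo reassignments; default 10000.
#' @param seed Integer RNG seed (Monte-Carlo mode).
#' @param alternative `"two_sided"` (default, compares |slope difference|),
#'   `"greater"` or `"less"` (signed, A minus B).
#' @param exhaustive Enumerate all `choose(nA+nB, nA)` reassignments
#'   instead of sampling; refused above `choose(20, 10)` assignments.
#' @param estimator Slope estimator inside the resampling loop:
#'   `"robust"` (IRLS bisquare, matching the observed statistic; default)
#'   or `"ols"` (much faster, classical).
#' @param plus_one If `TRUE`, use the (count+1)/(n_perm+1) small-sample
#'   correction; default `FALSE` (plain proportion).
#' @param psi,tuning,tol,max_iter Robust-fit controls, as [irls_fit()].
#' @return Object of class `"perm_test"`: `observed_delta` (slope A -
#'   slope B), `null_deltas`, `p_value`, `n_perm`, `alternative`, `seed`,
#'   `exhaustive`, `estimator`, `method`.
#' @examples
#' a <- simulate_skill_table(6, slope = 0.30, sigma = 0.02, seed = 1)
#' b <- simulate_skill_table(6, slope = 0.00, sigma = 0.02, seed = 2)
#' permutation_slope_test(a, b, n_perm = 200, seed = 3)
#' @export
permutation_slope_test <- function(groupA, groupB, n_perm = 10000,
                                   seed = NULL,
                                   alternative = c("two_sided", "greater",
                                                   "less"),
                                   exhaustive = FALSE,
                                   estimator = c("robust", "ols"),
                                   plus_one = FALSE,
                                   psi = "bisquare", tuning = 4.685,
                                   tol = 1e-8, max_iter = 100L) {
  alternative <- match.arg(alternative)
  estimator <- match.arg(estimator)
  sa <- as_series(groupA)
  sb <- as_series(groupB)
  if (!identical(sa$x, sb$x))
    stop("the two groups must share the same block numbers")
  nA <- nrow(sa$Y); nB <- nrow(sb$Y)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 subjects")
  x <- sa$x
  Y <- rbind(sa$Y, sb$Y)
  n <- nA + nB
  slope_of <- function(rows) pooled_slope(x, Y[rows, , drop = FALSE],
                                          estimator, psi, tuning, tol,
                                          max_iter)
  delta_of <- function(idxA) {
    slope_of(idxA) - slope_of(setdiff(seq_len(n), idxA))
  }
  observed <- delta_of(seq_len(nA))
  if (exhaustive) {
    total <- choose(n, nA)
    if (total > choose(20, 10))
      stop("exhaustive enumeration over ", total, " assignments is ",
           "impractical; use exhaustive = FALSE (Monte-Carlo) instead")
    assignments <- utils::combn(n, nA)
    null_deltas <- apply(assignments, 2, delta_of)
    n_used <- total
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_deltas <- vapply(seq_len(n_perm),
                          function(i) delta_of(sample.int(n, nA)),
                          numeric(1))
    n_used <- n_perm
  }
  extreme <- count_extreme(null_deltas, observed, alternative)
  p <- if (plus_one) (extreme + 1) / (n_used + 1) else extreme / n_used
  structure(list(observed_delta = observed, null_deltas = null_deltas,
                 p_value = p, n_perm = n_used, alternative = alternative,
                 seed = seed, exhaustive = exhaustive, estimator = estimator,
                 n_groups = c(nA, nB),
                 method = "subject reassignment between groups"),
            class = "perm_test")
}

#' Within-group permutation test for a day difference in learning rate
#'
#' Compares one group's learning rate between two days. The observed
#' statistic is the pooled slope on day 2 minus the pooled slope on day 1.
#' Because the same subjects contribute to both days, the null distribution
#' is built by within-subject day-label exchanges (sign-flip resampling):
#' each resample independently swaps, per subject, the day-1 and day-2
#' block series. The exchange scheme is this package's choice of
#' resampling plan for the paired design and is recorded in the result's
#' `method` field.
#'
#' @param day1,day2 Block-series tables for the same subjects on the two
#'   days (columns `subject`, `block`, `skill`).
#' @param n_perm,seed,alternative,exhaustive,estimator,plus_one,psi,tuning,tol,max_iter
#'   As in [permutation_slope_test()]; exhaustive mode enumerates all
#'   `2^n` flip patterns (refused above 2^20).
#' @return Object of class `"perm_test"` (observed_delta = day2 - day1).
#' @export
paired_day_slope_test <- function(day1, day2, n_perm = 10000, seed = NULL,
                                  alternative = c("two_sided", "greater",
                                                  "less"),
                                  exhaustive = FALSE,
                                  estimator = c("robust", "ols"),
                                  plus_one = FALSE,
                                  psi = "bisquare", tuning = 4.685,
                                  tol = 1e-8, max_iter = 100L) {
  alternative <- match.arg(alternative)
  estimator <- match.arg(estimator)
  s1 <- as_series(day1)
  s2 <- as_series(day2)
  if (!identical(s1$x, s2$x))
    stop("the two days must share the same block numbers")
  if (!identical(sort(rownames(s1$Y)), sort(rownames(s2$Y))))
    stop("'day1' and 'day2' must contain the same subjects")
  s2$Y <- s2$Y[rownames(s1$Y), , drop = FALSE]
  n <- nrow(s1$Y)
  x <- s1$x
  delta_of <- function(flip) {
    A <- s1$Y; B <- s2$Y
    if (any(flip)) {
      A[flip, ] <- s2$Y[flip, , drop = FALSE]
      B[flip, ] <- s1$Y[flip, , drop = FALSE]
    }
    pooled_slope(x, B, estimator, psi, tuning, tol, max_iter) -
      pooled_slope(x, A, estimator, psi, tuning, tol, max_iter)
  }
  observed <- delta_of(rep(FALSE, n))
  if (exhaustive) {
    total <- 2^n
    if (total > 2^20)
      stop("exhaustive enumeration over ", total, " flip patterns is ",
           "impractical; use exhaustive = FALSE (Monte-Carlo) instead")
    null_deltas <- vapply(seq_len(total) - 1, function(m) {
      delta_of(as.logical(bitwAnd(bitwShiftR(m, seq_len(n) - 1), 1L)))
    }, numeric(1))
    n_used <- total
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_deltas <- vapply(seq_len(n_perm), function(i) {
      delta_of(stats::runif(n) < 0.5)
    }, numeric(1))
    n_used <- n_perm
  }
  extreme <- count_extreme(null_deltas, observed, alternative)
  p <- if (plus_one) (extreme + 1) / (n_used + 1) else extreme / n_used
  structure(list(observed_delta = observed, null_deltas = null_deltas,
                 p_value = p, n_perm = n_used, alternative = alternative,
                 seed = seed, exhaustive = exhaustive, estimator = estimator,
                 n_groups = c(n, n),
                 method = "within-subject day-label exchange (sign flip)"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test on learning-rate difference\n")
  cat("  method: ", x$method, "\n", sep = "")
  cat(sprintf("  observed delta slope: %.4f\n", x$observed_delta))
  cat(sprintf("  p = %.4g  (%s%s, %d resamples, estimator = %s)\n",
              x$p_value, if (x$exhaustive) "exhaustive, " else "",
              x$alternative, x$n_perm, x$estimator))
  invisible(x)
}

#' @param x A `perm_test`.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further plot arguments.
#' @describeIn permutation_slope_test Histogram of the permutation null
#'   distribution with the observed slope difference marked by a dashed
#'   vertical line.
#' @export
plot.perm_test <- function(x, breaks = 30, ...) {
  graphics::hist(x$null_deltas, breaks = breaks, col = "grey80",
                 border = "white", main = "Permutation null distribution",
                 xlab = expression(Delta ~ "slope"), ...)
  graphics::abline(v = x$observed_delta, lty = 2, lwd = 2)
  invisible(x)
}
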