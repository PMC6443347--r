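#' Speed-accuracy skill score for the pinch-force task
#'
#' Combines a block's error rate and movement time into a single
#' dimensionless skill score
#' \deqn{a = \frac{1 - ER'}{ER' \, (\ln MT)^b}}
#' where \eqn{ER'} is the boundary-adjusted error rate, \eqn{MT} the block
#' movement time in seconds, and \eqn{b = 5.424} a task-specific constant
#' calibrated for the sequential isometric pinch task. Higher values mean
#' faster and/or more accurate performance; the score is strictly decreasing
#' in both the error rate and the movement time (for \eqn{MT > 1} s).
#'
#' The raw formula is undefined at error rates of exactly 0 or 1. Rates are
#' therefore shrunk to the interval
#' \eqn{[0.5/n, 1 - 0.5/n]} (a standard continuity correction on \eqn{n}
#' trials) before evaluation; see [adjust_error_rate()].
#'
#' @param error_rate Fraction of error trials in the block, in \[0, 1\].
#' @param movement_time Block movement time in seconds; must exceed 1 s
#'   (the non-integer exponent requires a positive logarithm).
#' @param b_exponent Task constant; default 5.424.
#' @param n_trials Number of trials behind `error_rate`, used for the
#'   boundary adjustment. Default 30 (one standard block).
#' @return Numeric vector of skill scores.
#' @examples
#' skill_measure(0.5, exp(1))        # exactly 1
#' skill_measure(0.2, 2.0)           # about 29.2
#' skill_measure(0, 2.0, n_trials = 30)  # finite, boundary-adjusted
#' @seealso [summarize_blocks()], [adjust_error_rate()]
#' @export
skill_measure <- function(error_rate, movement_time, b_exponent = 5.424,
                          n_trials = 30) {
  if (any(!is.finite(error_rate)) || any(error_rate < 0 | error_rate > 1))
    stop("'error_rate' must lie in [0, 1]")
  if (any(!is.finite(movement_time)) || any(movement_time <= 1))
    stop("'movement_time' must be > 1 s: ln(MT) must be positive for the ",
         "non-integer exponent")
  if (any(n_trials < 1)) stop("'n_trials' must be >= 1")
  er <- adjust_error_rate(error_rate, n_trials)
  (1 - er) / (er * log(movement_time)^b_exponent)
}

#' Boundary adjustment for block error rates
#'
#' Shrinks error rates of exactly 0 or 1 away from the boundary, where the
#' skill score is undefined: rates are clamped to
#' \eqn{[0.5/n, 1 - 0.5/n]} for a block of \eqn{n} trials. Interior rates
#' are returned unchanged, so the adjustment preserves monotonicity.
#'
#' @param error_rate Fraction(s) in \[0, 1\].
#' @param n_trials Trials per block behind each rate.
#' @return Adjusted rate(s) in the open interval (0, 1).
#' @export
adjust_error_rate <- function(error_rate, n_trials = 30) {
  eps <- 0.5 / n_trials
  pmin(pmax(error_rate, eps), 1 - eps)
}

.trial_cols <- c("subject", "group", "day", "block", "trial", "hand",
                 "movement_time", "g1", "g2", "g3", "g4", "g5", "is_error")
.gate_cols <- c("g1", "g2", "g3", "g4", "g5")

check_trials <- function(trials, require_single_block = FALSE) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("'trials' must be a non-empty data frame of trial records")
  missing <- setdiff(setdiff(.trial_cols, c("group", "hand")), names(trials))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- !as.matrix(trials[.gate_cols]) %in% c("H", "O", "U")
  if (any(bad))
    stop("gate outcomes must be coded H (hit), O (overshoot) or U (undershoot)")
  if (any(trials$movement_time <= 0)) stop("movement times must be positive")
  derived <- apply(trials[.gate_cols] != "H", 1, any)
  if (!all(derived == as.logical(trials$is_error)))
    stop("'is_error' inconsistent with gate outcomes: a trial is an error ",
         "iff any of the five targets was under- or overshot")
  if (require_single_block) {
    key <- unique(trials[c("subject", "day", "block")])
    if (nrow(key) != 1)
      stop("trials must all belong to one subject/day/block")
  }
  invisible(trials)
}

#' Summarise trials into per-block error rate, movement time and skill
#'
#' Aggregates a long trial table (one row per executed pinch trial) into one
#' row per subject/day/block holding the trial count, raw error rate
#' (fraction of trials with at least one of the five targets missed), the
#' block movement-time aggregate, and the skill score computed by
#' [skill_measure()] from the block's own error rate and movement time.
#'
#' @param trials Data frame with columns
#'   `subject, group, day, block, trial, hand, movement_time, g1..g5,
#'   is_error`; gate outcomes coded `"H"`, `"O"`, `"U"`.
#' @param b_exponent Skill-score exponent, default 5.424.
#' @param mt_aggregate How to aggregate trial movement times within a block:
#'   `"mean"` (default) or `"median"`.
#' @return Data frame with one row per subject/day/block:
#'   `subject, group, day, block, n_trials, error_rate, movement_time, skill`.
#' @examples
#' sim <- simulate_pinch_experiment(sim_config(), seed = 1)
#' head(summarize_blocks(sim$trials))
#' @export
summarize_blocks <- function(trials, b_exponent = 5.424,
                             mt_aggregate = c("mean", "median")) {
  mt_aggregate <- match.arg(mt_aggregate)
  check_trials(trials)
  agg_fun <- if (mt_aggregate == "mean") mean else stats::median
  if (is.null(trials$group)) trials$group <- NA_character_
  if (is.null(trials$hand)) trials$hand <- "right"
  key <- interaction(trials$subject, trials$group, trials$day, trials$block,
                     trials$hand, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(trials, key), function(d) {
    er <- mean(as.logical(d$is_error))
    mt <- agg_fun(d$movement_time)
    data.frame(subject = d$subject[1], group = d$group[1], day = d$day[1],
               block = d$block[1], hand = d$hand[1], n_trials = nrow(d),
               error_rate = er, movement_time = mt,
               skill = skill_measure(er, mt, b_exponent, nrow(d)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$subject, out$day, out$block), , drop = FALSE]
}

#' Decompose errors by force gate and direction
#'
#' For each of the five scored targets (gates 1-4 plus the end target),
#' computes the fraction of trials that hit, overshot or undershot that
#' target. Used to ask where along the force range errors concentrate and in
#' which direction -- under muscle fatigue, errors are expected to pile up
#' as overshoots at the low-force targets while the highest-force target is
#' comparatively spared.
#'
#' @param trials Trial table as for [summarize_blocks()].
#' @return Data frame with one row per gate: `gate, hit_rate,
#'   overshoot_rate, undershoot_rate` (rates sum to 1 within each gate).
#' @export
decompose_errors <- function(trials) {
  check_trials(trials)
  out <- do.call(rbind, lapply(seq_along(.gate_cols), function(g) {
    x <- trials[[.gate_cols[g]]]
    data.frame(gate = g,
               hit_rate = mean(x == "H"),
               overshoot_rate = mean(x == "O"),
               undershoot_rate = mean(x == "U"))
  }))
  rownames(out) <- NULL
  out
}

#' Summarise sequence-task trials per block
#'
#' For the 10-element keyboard sequence task, aggregates trial rows into one
#' row per subject/day/block with the block error rate (fraction of trials
#' that were not errorless, i.e. contained at least one wrong key press) and
#' the mean movement time (first to tenth correct press).
#'
#' @param trials Data frame with columns
#'   `subject, group, day, block, trial, movement_time, n_wrong_presses`.
#' @return Data frame `subject, group, day, block, n_trials, error_rate,
#'   movement_time`.
#' @export
summarize_sequence_blocks <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("'trials' must be a non-empty data frame")
  need <- c("subject", "day", "block", "movement_time", "n_wrong_presses")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("sequence table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(trials$n_wrong_presses < 0))
    stop("'n_wrong_presses' must be non-negative")
  if (is.null(trials$group)) trials$group <- NA_character_
  key <- interaction(trials$subject, trials$day, trials$block, drop = TRUE,
                     lex.order = TRUE)
  out <- do.call(rbind, lapply(split(trials, key), function(d) {
    data.frame(subject = d$subject[1], group = d$group[1], day = d$day[1],
               block = d$block[1], n_trials = nrow(d),
               error_rate = 1 - mean(d$n_wrong_presses == 0),
               movement_time = mean(d$movement_time))
  }))
  rownames(out) <- NULL
  out[order(out$subject, out$day, out$block), , drop = FALSE]
}
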