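# Synthetic-data generator emulating the behavioural structure of
# fatigue/skill-learning experiments: groups x days x 4 blocks x 30 trials,
# group-specific learning rates on the skill scale, fatigue-induced
# overshoot concentrated at the low-force gates, exponential MVC decline
# during sustained contraction, and a 10-element sequence task.

#' Default gate force windows
#'
#' The five scored targets (gates 1-4 plus the end target) as force
#' windows expressed in fractions of MVC. Gate 2 requires the largest
#' force; its upper limit is 40\% of MVC, the ceiling of the task's force
#' range. Window half-width defaults to 12\% of the target force (the
#' accuracy tolerance around each target).
#'
#' @param centers Target force fractions for gates 1-4 and the end target.
#' @param half_width Relative window half-width.
#' @return List with `center`, `lower`, `upper` (fractions of MVC) and
#'   `half_width`.
#' @export
default_gate_windows <- function(centers = c(0.14, 0.4 / 1.12, 0.22,
                                             0.30, 0.09),
                                 half_width = 0.12) {
  if (length(centers) != 5) stop("exactly 5 gate centers are required")
  upper <- centers * (1 + half_width)
  if (any(centers <= 0) || any(upper > 0.4 + 1e-12))
    stop("gate windows must stay within (0, 0.4] of MVC")
  list(center = centers, lower = centers * (1 - half_width),
       upper = pmin(upper, 0.4), half_width = half_width)
}

#' Logarithmic force-to-cursor transduction
#'
#' The cursor position on screen follows a logarithmic transduction of the
#' applied pinch force: `x = k * ln(1 + force / f0)`, strictly increasing
#' with `x(0) = 0`. [invert_transduction()] is its exact algebraic inverse.
#'
#' @param force Force in Newton (>= 0).
#' @param k,f0 Transduction gain (screen units) and force scale (N).
#' @return Cursor position(s) in screen units.
#' @export
transduce_force <- function(force, k = 1, f0 = 1) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("'force' must be finite and non-negative")
  k * log1p(force / f0)
}

#' @rdname transduce_force
#' @param position Cursor position(s) in screen units.
#' @export
invert_transduction <- function(position, k = 1, f0 = 1) {
  f0 * expm1(position / k)
}

# Deterministic per-subject RNG substream seed. Built so that adding a
# subject (or a group) never perturbs the draws of existing subjects.
subject_seed <- function(seed, label, i) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 1e6
  (abs(seed) * 1013 + h * 131 + i * 7919) %% 2147483629 + 1
}

#' Simulation configuration for the pinch-force experiment
#'
#' Collects, validates and defaults every generative parameter of the
#' synthetic pinch-task experiment. Defaults emulate the two-group,
#' two-day design (fatigue group of 20, control group of 18, 4 blocks of
#' 30 trials per day) with group learning-rate presets on the skill scale
#' of the magnitude reported for this task family (about 0.17 per block
#' for rested controls on day 1 versus about 0.04 under fatigue); these
#' are plausible presets, not ground truth about any real dataset.
#'
#' @param groups Named list; each element a list with `n_subjects`,
#'   `baseline_skill`, `skill_slope` (per-day vector, recycled), and
#'   `fatigued_days` (integer vector of days on which this group trains
#'   fatigued).
#' @param days,blocks_per_day,trials_per_block Design dimensions.
#' @param subject_sd,block_sd SD of the subject-level random intercept and
#'   of block-level noise, both on the skill scale.
#' @param mt Movement-time model: `start` (mean of block 1, s), `decay`
#'   (multiplicative per block), `sdlog` (lognormal sigma), `floor`
#'   (lower bound, > 1 s so that ln(MT) > 0).
#' @param gates Gate windows, see [default_gate_windows()].
#' @param overshoot_beta Fatigue force bias: on fatigued days the executed
#'   force at a target of fraction `f` is biased upward by
#'   `beta * (1 - f / max(f))` (relative), largest at the weakest targets
#'   -- the sensory-attenuation signature of post-contraction force
#'   misestimation.
#' @param mvc MVC model: `baseline` (N), `decay_rate` (1/s, exponential
#'   decline during sustained contraction; default calibrated so force
#'   falls to 40\% of MVC in about 69 s), `noise_sd` (N),
#'   `sampling_rate` (Hz).
#' @param transduction `k` and `f0` of [transduce_force()].
#' @param day_carryover Fraction of a day's skill gain retained at the
#'   start of the next day.
#' @param b_exponent Skill-score exponent.
#' @return Validated config list of class `"sim_config"`.
#' @export
sim_config <- function(groups = NULL, days = 2, blocks_per_day = 4,
                       trials_per_block = 30, subject_sd = 0.10,
                       block_sd = 0.05,
                       mt = list(start = 4.5, decay = 0.97, sdlog = 0.15,
                                 floor = 1.2),
                       gates = default_gate_windows(),
                       overshoot_beta = 0.08,
                       mvc = list(baseline = 100,
                                  decay_rate = log(2.5) / 68.91,
                                  noise_sd = 1, sampling_rate = 50),
                       transduction = list(k = 1, f0 = 1),
                       day_carryover = 0.8, b_exponent = 5.424) {
  if (is.null(groups))
    groups <- list(
      NoFTG = list(n_subjects = 18, baseline_skill = 0.30,
                   skill_slope = c(0.169, 0.339),
                   fatigued_days = integer(0)),
      FTG = list(n_subjects = 20, baseline_skill = 0.30,
                 skill_slope = c(0.038, 0.083), fatigued_days = 1L))
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("invalid config field 'groups': groups must be named")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n_subjects) || gr$n_subjects < 1)
      stop("invalid config field 'groups$", g, "$n_subjects'")
    if (is.null(gr$baseline_skill) || gr$baseline_skill <= 0)
      stop("invalid config field 'groups$", g, "$baseline_skill'")
    if (is.null(gr$skill_slope))
      stop("invalid config field 'groups$", g, "$skill_slope'")
    if (is.null(gr$fatigued_days)) groups[[g]]$fatigued_days <- integer(0)
  }
  if (days < 1 || blocks_per_day < 1 || trials_per_block < 1)
    stop("invalid config field 'days'/'blocks_per_day'/'trials_per_block'")
  if (mt$floor <= 1)
    stop("invalid config field 'mt$floor': must exceed 1 s so ln(MT) > 0")
  if (mt$start <= mt$floor) stop("invalid config field 'mt$start'")
  if (mt$decay <= 0 || mt$decay > 1) stop("invalid config field 'mt$decay'")
  if (subject_sd < 0 || block_sd < 0)
    stop("invalid config field 'subject_sd'/'block_sd'")
  if (overshoot_beta < 0 || overshoot_beta >= gates$half_width)
    stop("invalid config field 'overshoot_beta': must lie in [0, ",
         "half_width) so the biased mean force stays inside the window")
  if (mvc$baseline <= 0 || mvc$decay_rate < 0 || mvc$noise_sd < 0)
    stop("invalid config field 'mvc'")
  if (day_carryover < 0 || day_carryover > 1)
    stop("invalid config field 'day_carryover'")
  structure(list(groups = groups, days = days,
                 blocks_per_day = blocks_per_day,
                 trials_per_block = trials_per_block,
                 subject_sd = subject_sd, block_sd = block_sd, mt = mt,
                 gates = gates, overshoot_beta = overshoot_beta, mvc = mvc,
                 transduction = transduction,
                 day_carryover = day_carryover, b_exponent = b_exponent),
            class = "sim_config")
}

# Any-gate miss probability for a given force-noise coefficient of
# variation, and its calibration so the trial error probability matches
# the skill-model-implied block error probability.
gate_hit_prob <- function(cv, gates, bias) {
  m <- gates$center * (1 + bias)
  sd <- pmax(cv * gates$center, 1e-12)
  stats::pnorm((gates$upper - m) / sd) - stats::pnorm((gates$lower - m) / sd)
}

calibrate_cv <- function(p_err, gates, bias) {
  total <- function(cv) 1 - prod(gate_hit_prob(cv, gates, bias))
  lo <- 1e-6
  if (total(lo) >= p_err) return(lo)
  stats::uniroot(function(cv) total(cv) - p_err, c(lo, 5),
                 tol = 1e-10)$root
}

#' Simulate a full pinch-task experiment at trial level
#'
#' Generates a long trial table with the full generative structure: each
#' subject carries a random skill intercept; each block has a target skill
#' level (group baseline + learning-rate gain + day carryover + noise)
#' which, combined with the block's expected movement time, implies a
#' block error probability through the inverse of the skill formula. At
#' trial level, movement times are drawn from a decaying shifted-lognormal
#' model (floored above 1.2 s) and the executed force at each of the five
#' gates is the target force biased multiplicatively upward under fatigue
#' (more at low-force targets) plus signal-dependent Gaussian noise; the
#' outcome is classified against the gate window and a trial is an error
#' iff any gate is missed. The force-noise coefficient of variation is
#' calibrated per block so the implied any-gate miss probability equals
#' the skill-model error probability.
#'
#' Randomness is drawn from per-subject substreams spawned from the master
#' seed, so adding a subject or group never changes existing subjects'
#' data, and the same seed reproduces the table exactly.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return List with `trials` (data frame in the standard trial dialect:
#'   `subject, group, day, block, trial, hand, movement_time, g1..g5,
#'   is_error`) and `truth` (per group/day/block target skill, expected
#'   movement time and error probability, plus the config).
#' @export
simulate_pinch_experiment <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  B <- config$blocks_per_day
  Tn <- config$trials_per_block
  gates <- config$gates
  rel <- 1 - gates$center / max(gates$center)
  rows <- list()
  truth_rows <- list()
  for (gname in names(config$groups)) {
    gr <- config$groups[[gname]]
    slopes <- rep(gr$skill_slope, length.out = config$days)
    for (i in seq_len(gr$n_subjects)) {
      set.seed(subject_seed(seed, gname, i))
      subj <- sprintf("%s_%02d", gname, i)
      u_s <- stats::rnorm(1, 0, config$subject_sd)
      for (d in seq_len(config$days)) {
        gain_prev <- if (d > 1)
          sum(slopes[seq_len(d - 1)]) * B * config$day_carryover else 0
        fatigued <- d %in% gr$fatigued_days
        bias <- if (fatigued) config$overshoot_beta * rel else rep(0, 5)
        for (b in seq_len(B)) {
          bindex <- (d - 1) * B + b
          mu_mt <- config$mt$floor +
            (config$mt$start - config$mt$floor) * config$mt$decay^(bindex - 1)
          a_pop <- gr$baseline_skill + gain_prev + slopes[d] * b
          a <- max(a_pop + u_s + stats::rnorm(1, 0, config$block_sd), 0.01)
          p_err <- 1 / (1 + a * log(mu_mt)^config$b_exponent)
          cv <- calibrate_cv(p_err, gates, bias)
          mts <- config$mt$floor +
            stats::rlnorm(Tn, log(mu_mt - config$mt$floor) -
                            config$mt$sdlog^2 / 2, config$mt$sdlog)
          m <- gates$center * (1 + bias)
          z <- matrix(stats::rnorm(Tn * 5), Tn, 5)
          forces <- sweep(sweep(z, 2, cv * gates$center, `*`), 2, m, `+`)
          out <- matrix("H", Tn, 5)
          out[sweep(forces, 2, gates$upper, `>`)] <- "O"
          out[sweep(forces, 2, gates$lower, `<`)] <- "U"
          rows[[length(rows) + 1]] <- data.frame(
            subject = subj, group = gname, day = d, block = b,
            trial = seq_len(Tn), hand = "right", movement_time = mts,
            g1 = out[, 1], g2 = out[, 2], g3 = out[, 3], g4 = out[, 4],
            g5 = out[, 5],
            is_error = apply(out != "H", 1, any))
          if (i == 1)
            truth_rows[[length(truth_rows) + 1]] <- data.frame(
              group = gname, day = d, block = b, target_skill = a_pop,
              mt_mean = mu_mt,
              error_prob = 1 / (1 + a_pop * log(mu_mt)^config$b_exponent),
              fatigued = fatigued)
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials,
       truth = list(config = config,
                    blocks = do.call(rbind, truth_rows),
                    seed = seed))
}

#' Simulate a skill table directly on the skill scale
#'
#' The block-level counterpart of [simulate_pinch_experiment()]: one skill
#' score per subject per block, equal to `baseline + slope * block` plus
#' iid Gaussian noise. This is the generator used to study the estimator
#' itself (slope recovery, permutation-test calibration and power), where
#' the trial-level machinery would only add nuisance variance.
#'
#' @param n_subjects Number of subjects.
#' @param slope True learning rate (skill units per block).
#' @param baseline Skill intercept.
#' @param sigma SD of the additive noise on each block score.
#' @param blocks Block numbers (default 1:4).
#' @param seed Master seed (per-subject substreams, as everywhere).
#' @param group Optional group label column.
#' @param subject_prefix Prefix for subject identifiers.
#' @return Data frame `subject, group, block, skill`.
#' @export
simulate_skill_table <- function(n_subjects, slope, baseline = 0.3,
                                 sigma = 0.05, blocks = 1:4, seed = NULL,
                                 group = NULL,
                                 subject_prefix = group %||% "s") {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  rows <- lapply(seq_len(n_subjects), function(i) {
    set.seed(subject_seed(seed, subject_prefix, i))
    data.frame(subject = sprintf("%s_%02d", subject_prefix, i),
               group = group %||% NA_character_, block = blocks,
               skill = baseline + slope * blocks +
                 stats::rnorm(length(blocks), 0, sigma))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a sustained-contraction force trace
#'
#' Fatigue mode: exponential force decline `F(t) = mvc * exp(-decay_rate *
#' t)` plus Gaussian transducer noise, floored at 0 N. Control mode: a
#' flat trace at 5\% of MVC (the non-fatiguing matched contraction), plus
#' noise.
#'
#' @param mvc MVC in Newton.
#' @param decay_rate Exponential decline rate (1/s).
#' @param duration Trace length in seconds.
#' @param noise_sd Gaussian noise SD in Newton (0 for a noiseless trace).
#' @param sampling_rate Hz.
#' @param seed Optional seed.
#' @param mode `"fatigue"` (default) or `"control"`.
#' @return A [force_trace()].
#' @export
simulate_force_trace <- function(mvc, decay_rate, duration, noise_sd = 0,
                                 sampling_rate = 100, seed = NULL,
                                 mode = c("fatigue", "control")) {
  mode <- match.arg(mode)
  if (mvc <= 0 || duration <= 0 || decay_rate < 0 || noise_sd < 0 ||
      sampling_rate <= 0)
    stop("'mvc', 'duration' and 'sampling_rate' must be positive; ",
         "'decay_rate' and 'noise_sd' non-negative")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / sampling_rate)
  t <- t[-length(t)]
  f <- if (mode == "fatigue") mvc * exp(-decay_rate * t)
       else rep(0.05 * mvc, length(t))
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), 0, noise_sd)
  force_trace(pmax(f, 0), sampling_rate)
}

#' Sequence-task simulation configuration
#'
#' Parameters of the 10-element keyboard sequence task generator. Both
#' groups share identical parameters by default: fatigue had no measurable
#' effect on this task, so the generator's null structure mirrors that.
#'
#' @param groups Named list of `list(n_subjects = ...)`.
#' @param days,blocks_per_day,trials_per_block Design dimensions.
#' @param press Per-press timing model: `mean_start` (s), `block_decay`
#'   (multiplicative per block), `sdlog` (lognormal sigma).
#' @param press_error Per-press wrong-key probability: `start`,
#'   `block_decay`.
#' @param n_elements Sequence length (10).
#' @return Config list of class `"seq_config"`.
#' @export
sim_sequence_config <- function(groups = list(
                                  NoFTG_SEQ = list(n_subjects = 9),
                                  FTG_SEQ = list(n_subjects = 9)),
                                days = 2, blocks_per_day = 4,
                                trials_per_block = 30,
                                press = list(mean_start = 0.5,
                                             block_decay = 0.93,
                                             sdlog = 0.2),
                                press_error = list(start = 0.03,
                                                   block_decay = 0.9),
                                n_elements = 10) {
  if (is.null(names(groups))) stop("invalid config field 'groups'")
  if (press$mean_start <= 0 || press$sdlog < 0 ||
      press$block_decay <= 0 || press$block_decay > 1)
    stop("invalid config field 'press'")
  if (press_error$start < 0 || press_error$start > 1)
    stop("invalid config field 'press_error$start'")
  structure(list(groups = groups, days = days,
                 blocks_per_day = blocks_per_day,
                 trials_per_block = trials_per_block, press = press,
                 press_error = press_error, n_elements = n_elements),
            class = "seq_config")
}

#' Simulate the 10-element sequence task
#'
#' Per trial, the movement time is the sum of `n_elements` per-press
#' shifted-lognormal times whose mean declines per block (practice), and
#' the number of wrong presses is binomial with a per-press error
#' probability that also declines per block. A trial is errorless iff it
#' contains no wrong press. Wrong presses pause the sequence but do not
#' enter the movement time, which is defined over the correct presses.
#'
#' @param config A [sim_sequence_config()].
#' @param seed Master seed.
#' @return Data frame `subject, group, day, block, trial, movement_time,
#'   n_wrong_presses`.
#' @export
simulate_sequence_experiment <- function(config = sim_sequence_config(),
                                         seed = 1) {
  stopifnot(inherits(config, "seq_config"))
  B <- config$blocks_per_day
  Tn <- config$trials_per_block
  rows <- list()
  for (gname in names(config$groups)) {
    gr <- config$groups[[gname]]
    for (i in seq_len(gr$n_subjects)) {
      set.seed(subject_seed(seed, gname, i))
      subj <- sprintf("%s_%02d", gname, i)
      for (d in seq_len(config$days)) {
        for (b in seq_len(B)) {
          bindex <- (d - 1) * B + b
          mean_press <- config$press$mean_start *
            config$press$block_decay^(bindex - 1)
          p_wrong <- config$press_error$start *
            config$press_error$block_decay^(bindex - 1)
          mt <- vapply(seq_len(Tn), function(tr) {
            if (config$press$sdlog == 0)
              mean_press * config$n_elements
            else
              sum(stats::rlnorm(config$n_elements,
                                log(mean_press) -
                                  config$press$sdlog^2 / 2,
                                config$press$sdlog))
          }, numeric(1))
          wrong <- stats::rbinom(Tn, config$n_elements, p_wrong)
          rows[[length(rows) + 1]] <- data.frame(
            subject = subj, group = gname, day = d, block = b,
            trial = seq_len(Tn), movement_time = mt,
            n_wrong_presses = wrong)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
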