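# Orchestration of the four experiment designs: simulate (or load) trial
# data, summarise to blocks, fit learning curves, run the planned
# comparisons, and bundle the results with provenance.

#' Experiment specification
#'
#' Packaged per-experiment presets mirroring the four study designs:
#' \describe{
#'   \item{1}{Fatigue vs control, 2 groups (20/18), 2 days (optionally 4
#'     with 12 per group), per-day group comparison of learning rates,
#'     movement-time/error-rate ANOVAs, fatigue summaries.}
#'   \item{2}{Intermanual transfer: 2 groups of 10, one day of right-hand
#'     training plus left-hand pre/post blocks (15 trials each); adds the
#'     left-hand block2 - block1 transfer comparison.}
#'   \item{3}{Three groups (10/15/15: rested sham, fatigued sham, fatigued
#'     M1-stimulated), 2 days; three pairwise group comparisons per day
#'     plus three within-group across-day comparisons.}
#'   \item{4}{Sequence task: 2 groups of 9, 2 days; block-by-group ANOVAs
#'     on error rate and movement time only (no permutation tests).}
#' }
#'
#' @param experiment Integer 1-4.
#' @param n_perm Permutation count for all comparisons (default 10000).
#' @param seed Master seed: drives both simulation and resampling.
#' @param days Override the preset number of days (experiment 1 only:
#'   2 or 4).
#' @param input `"simulate"` (default) or `"load"`.
#' @param path Directory with `trials.csv` (and `sequence.csv` for
#'   experiment 4) when `input = "load"`.
#' @param estimator Slope estimator inside permutation loops
#'   (`"robust"`/`"ols"`).
#' @param config Optional [sim_config()] / [sim_sequence_config()]
#'   override.
#' @return Object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(experiment, n_perm = 10000, seed = 1,
                            days = NULL, input = c("simulate", "load"),
                            path = NULL,
                            estimator = c("robust", "ols"),
                            config = NULL) {
  input <- match.arg(input)
  estimator <- match.arg(estimator)
  if (!experiment %in% 1:4)
    stop("unknown experiment id: ", experiment, " (must be 1, 2, 3 or 4)")
  if (input == "load" && is.null(path))
    stop("'path' is required when input = \"load\"")
  if (is.null(config)) config <- default_experiment_config(experiment, days)
  days <- if (!is.null(config$days)) config$days else days
  structure(list(experiment = as.integer(experiment), n_perm = n_perm,
                 seed = as.integer(seed), days = days, input = input,
                 path = path, estimator = estimator, config = config),
            class = "experiment_spec")
}

default_experiment_config <- function(experiment, days = NULL) {
  switch(as.character(experiment),
    "1" = {
      d <- days %||% 2
      if (!d %in% c(2, 4)) stop("experiment 1 runs 2 or 4 days")
      n <- if (d == 4) c(12, 12) else c(18, 20)
      sim_config(groups = list(
        NoFTG = list(n_subjects = n[1], baseline_skill = 0.30,
                     skill_slope = c(0.169, 0.339, 0.30, 0.25),
                     fatigued_days = integer(0)),
        FTG = list(n_subjects = n[2], baseline_skill = 0.30,
                   skill_slope = c(0.038, 0.083, 0.20, 0.22),
                   fatigued_days = 1L)), days = d)
    },
    "2" = sim_config(groups = list(
        NoFTG_TR = list(n_subjects = 10, baseline_skill = 0.30,
                        skill_slope = 0.030, fatigued_days = integer(0)),
        FTG_TR = list(n_subjects = 10, baseline_skill = 0.30,
                      skill_slope = 0.008, fatigued_days = 1L)),
      days = 1),
    "3" = sim_config(groups = list(
        NoFTG_SHAM = list(n_subjects = 10, baseline_skill = 0.30,
                          skill_slope = c(0.049, 0.040),
                          fatigued_days = integer(0)),
        FTG_SHAM = list(n_subjects = 15, baseline_skill = 0.30,
                        skill_slope = c(0.020, 0.022), fatigued_days = 1L),
        FTG_M1 = list(n_subjects = 15, baseline_skill = 0.30,
                      skill_slope = c(0.016, 0.042), fatigued_days = 1L)),
      days = 2),
    "4" = sim_sequence_config())
}

# Left-hand transfer presets for experiment 2: pre/post skill deltas of
# the untrained hand (block 2 - block 1), per group.
transfer_presets <- list(NoFTG_TR = 0.133, FTG_TR = 0.018)

#' Run an experiment end to end
#'
#' Executes the stage graph of the given [experiment_spec()]: obtain trial
#' data (simulate with the spec's seed, or load), summarise to block level,
#' fit learning curves per group and day, run every comparison in the
#' experiment's analysis plan (permutation tests on learning rates,
#' transfer deltas, ANOVAs on movement time and error rate), and -- for
#' designs with a fatigue induction -- quantify MVC decrement and time to
#' fatigue from simulated force traces.
#'
#' @param spec An [experiment_spec()].
#' @return Object of class `"results_bundle"` with components
#'   `block_summaries`, `fits` (per group-day table), `perm_results`
#'   (named list of [permutation_slope_test()] results),
#'   `anova_tables` (named list), `fatigue` (per-subject data frame or
#'   NULL), `transfer` (experiment 2 only), and `provenance`
#'   (experiment id, seed, config hash, package version).
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (spec$experiment == 4) return(run_sequence_experiment(spec))
  config <- spec$config
  if (spec$input == "simulate") {
    sim <- simulate_pinch_experiment(config, seed = spec$seed)
    trials <- sim$trials
  } else {
    trials <- read_trials(file.path(spec$path, "trials.csv"))
  }
  bs <- summarize_blocks(trials)
  fits <- fit_learning_by(bs)
  attr(fits, "fits") <- NULL   # keep the bundle a plain serialisable table
  groups <- names(config$groups)
  days <- sort(unique(bs$day))
  perm <- list()
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  for (d in days) {
    for (pr in pairs) {
      nm <- sprintf("day%d_%s_vs_%s", d, pr[1], pr[2])
      perm[[nm]] <- permutation_slope_test(
        bs[bs$group == pr[1] & bs$day == d, ],
        bs[bs$group == pr[2] & bs$day == d, ],
        n_perm = spec$n_perm, seed = spec$seed + 1000 * d +
          match(list(pr), pairs), estimator = spec$estimator)
    }
  }
  if (spec$experiment == 3 && length(days) > 1) {
    for (g in groups) {
      nm <- sprintf("%s_day%d_vs_day%d", g, days[2], days[1])
      perm[[nm]] <- paired_day_slope_test(
        bs[bs$group == g & bs$day == days[1], ],
        bs[bs$group == g & bs$day == days[2], ],
        n_perm = spec$n_perm, seed = spec$seed + 77 + match(g, groups),
        estimator = spec$estimator)
    }
  }
  anovas <- list()
  for (d in days) {
    for (dv in c("movement_time", "error_rate")) {
      anovas[[sprintf("day%d_%s", d, dv)]] <-
        mixed_anova(bs[bs$day == d, ], dv = dv)
    }
  }
  transfer <- NULL
  if (spec$experiment == 2 && spec$input == "simulate") {
    transfer <- run_transfer_stage(spec, groups)
    perm[["left_hand_transfer"]] <- transfer$perm
  }
  fat <- if (spec$input == "simulate") run_fatigue_stage(spec, config)
         else NULL
  bundle <- structure(list(block_summaries = bs, fits = fits,
                           perm_results = perm, anova_tables = anovas,
                           fatigue = fat,
                           transfer = transfer$table %||% NULL,
                           provenance = provenance_of(spec)),
                      class = "results_bundle")
  bundle
}

# Left-hand pre/post blocks (15 trials each) for experiment 2: simulated
# directly on the skill scale, then compared by subject-level permutation
# of the two-block series. With only two blocks the learning measure is
# the per-subject block2 - block1 delta, and the pooled OLS slope equals
# the group mean delta exactly, so the permutation statistic is computed
# with the plain estimator.
run_transfer_stage <- function(spec, groups) {
  tabs <- lapply(groups, function(g) {
    simulate_skill_table(
      n_subjects = spec$config$groups[[g]]$n_subjects,
      slope = transfer_presets[[g]] %||% 0.05,
      baseline = 0.25, sigma = 0.04, blocks = c(1, 2),
      seed = spec$seed + 13, group = g,
      subject_prefix = paste0(g, "_left"))
  })
  names(tabs) <- groups
  deltas <- lapply(tabs, function(tab) {
    vapply(split(tab, tab$subject), function(d) {
      pre <- d[d$block == 1, ]; post <- d[d$block == 2, ]
      transfer_delta(pre, post)
    }, numeric(1))
  })
  pt <- permutation_slope_test(tabs[[1]], tabs[[2]], n_perm = spec$n_perm,
                               seed = spec$seed + 29, estimator = "ols")
  table <- do.call(rbind, lapply(groups, function(g)
    data.frame(group = g, subject = names(deltas[[g]]),
               delta = deltas[[g]], row.names = NULL)))
  list(table = table, perm = pt)
}

# MVC and time-to-fatigue for every subject of every group with a fatigue
# induction on day 1; control groups get the flat 5%-MVC contraction and
# no decrement beyond noise.
run_fatigue_stage <- function(spec, config) {
  rows <- list()
  for (g in names(config$groups)) {
    gr <- config$groups[[g]]
    fatigued <- length(gr$fatigued_days) > 0
    for (i in seq_len(gr$n_subjects)) {
      sseed <- subject_seed(spec$seed + 5000, g, i)
      set.seed(sseed)
      mvc_pre <- config$mvc$baseline + stats::rnorm(1, 0, 5)
      thr <- gate2_threshold(mvc_pre)
      if (fatigued) {
        trace <- simulate_force_trace(mvc_pre, config$mvc$decay_rate,
                                      duration = 180,
                                      noise_sd = config$mvc$noise_sd,
                                      sampling_rate = config$mvc$sampling_rate,
                                      seed = sseed + 1)
        ttf <- time_to_fatigue(trace, thr)
        mvc_post <- thr
      } else {
        ttf <- NA_real_
        mvc_post <- mvc_pre * (1 - stats::runif(1, 0, 0.03))
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = g, subject = sprintf("%s_%02d", g, i), mvc_pre = mvc_pre,
        mvc_post = mvc_post,
        decrement = fatigue_decrement(mvc_pre, mvc_post),
        threshold_force = thr, time_to_fatigue = ttf, fatigued = fatigued)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_sequence_experiment <- function(spec) {
  config <- spec$config
  trials <- if (spec$input == "simulate")
    simulate_sequence_experiment(config, seed = spec$seed)
  else read_sequence_trials(file.path(spec$path, "sequence.csv"))
  bs <- summarize_sequence_blocks(trials)
  anovas <- list()
  for (d in sort(unique(bs$day))) {
    for (dv in c("error_rate", "movement_time")) {
      anovas[[sprintf("day%d_%s", d, dv)]] <-
        mixed_anova(bs[bs$day == d, ], dv = dv)
    }
  }
  structure(list(block_summaries = bs, fits = NULL, perm_results = list(),
                 anova_tables = anovas, fatigue = NULL, transfer = NULL,
                 provenance = provenance_of(spec)),
            class = "results_bundle")
}

# 32-bit FNV-1a hash of the deparsed spec: changes iff any
# analysis-relevant field changes.
config_hash <- function(spec) {
  txt <- paste(deparse(spec[c("experiment", "n_perm", "seed", "days",
                              "input", "estimator", "config")]),
               collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_of <- function(spec) {
  list(experiment = spec$experiment, seed = spec$seed,
       n_perm = spec$n_perm, estimator = spec$estimator,
       config_hash = config_hash(spec),
       package_version = as.character(utils::packageVersion("motorskill")))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Results bundle (experiment ", x$provenance$experiment, ", seed ",
      x$provenance$seed, ", config ", x$provenance$config_hash, ")\n",
      sep = "")
  cat("  block summaries: ", nrow(x$block_summaries), " rows\n", sep = "")
  if (!is.null(x$fits)) {
    cat("  learning fits:\n")
    print(x$fits, row.names = FALSE)
  }
  if (length(x$perm_results)) {
    cat("  permutation comparisons:\n")
    for (nm in names(x$perm_results)) {
      pr <- x$perm_results[[nm]]
      cat(sprintf("    %-28s delta = %8.4f  p = %.4g\n", nm,
                  pr$observed_delta, pr$p_value))
    }
  }
  cat("  ANOVA tables: ", length(x$anova_tables), "\n", sep = "")
  if (!is.null(x$fatigue)) {
    f <- x$fatigue[x$fatigue$fatigued, ]
    if (nrow(f))
      cat(sprintf("  fatigue: mean decrement %.2f, mean time to fatigue %.1f s\n",
                  mean(f$decrement), mean(f$time_to_fatigue, na.rm = TRUE)))
  }
  invisible(x)
}

#' Read / write the standard trial CSV dialect
#'
#' Long-format trial tables with header
#' `subject,group,day,block,trial,hand,movement_time,g1,g2,g3,g4,g5,is_error`
#' and gate outcomes coded `H`/`O`/`U`. Reading validates the header, the
#' outcome codes and the `is_error` consistency, reporting the offending
#' column or row; writing formats movement times at full precision so that
#' a write-read round trip reproduces the table exactly.
#'
#' @param path CSV file path.
#' @return `read_trials`: the validated trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_cols, names(df))
  if (length(missing))
    stop("malformed trial CSV: missing column(s) ",
         paste(missing, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$group <- as.character(df$group)
  gate_mat <- as.matrix(df[.gate_cols])
  bad <- which(!gate_mat %in% c("H", "O", "U"))
  if (length(bad)) {
    row <- (bad[1] - 1) %% nrow(df) + 1
    stop("malformed trial CSV: invalid gate outcome '",
         gate_mat[bad[1]], "' at data row ", row,
         " (must be H, O or U)")
  }
  df$is_error <- as.logical(df$is_error)
  check_trials(df)
  df
}

#' @rdname read_trials
#' @param trials Trial data frame in the standard dialect.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  out <- trials[.trial_cols]
  out$movement_time <- sprintf("%.17g", out$movement_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the sequence-task CSV dialect
#'
#' Header: `subject,group,day,block,trial,movement_time,n_wrong_presses`.
#'
#' @param path CSV file path.
#' @return `read_sequence_trials`: the validated data frame.
#' @export
read_sequence_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "day", "block", "trial", "movement_time",
            "n_wrong_presses")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("malformed sequence CSV: missing column(s) ",
         paste(missing, collapse = ", "))
  df$subject <- as.character(df$subject)
  df
}

#' @rdname read_sequence_trials
#' @param trials Sequence trial data frame.
#' @export
write_sequence_trials <- function(trials, path) {
  out <- trials[c("subject", "group", "day", "block", "trial",
                  "movement_time", "n_wrong_presses")]
  out$movement_time <- sprintf("%.17g", out$movement_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a results bundle as JSON
#'
#' Serialises a [run_experiment()] bundle (including permutation null
#' distributions, so reports can be regenerated) to a single JSON file
#' and restores it losslessly.
#'
#' @param bundle A `results_bundle`.
#' @param path JSON file path.
#' @param include_null Keep the permutation null distributions (default
#'   `TRUE`; needed to re-plot histograms from a stored bundle).
#' @return `read_bundle`: the restored `results_bundle`.
#' @export
write_bundle <- function(bundle, path, include_null = TRUE) {
  stopifnot(inherits(bundle, "results_bundle"))
  ser <- unclass(bundle)
  ser$perm_results <- lapply(ser$perm_results, function(pr) {
    pr <- unclass(pr)
    if (!include_null) pr$null_deltas <- NULL
    pr
  })
  ser$anova_tables <- lapply(ser$anova_tables, function(a) {
    list(table = as.data.frame(a), epsilon = attr(a, "epsilon"),
         design = as.list(attr(a, "design")))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  ser$block_summaries <- as.data.frame(ser$block_summaries)
  if (!is.null(ser$fits)) ser$fits <- as.data.frame(ser$fits)
  if (!is.null(ser$fatigue)) {
    ser$fatigue <- as.data.frame(ser$fatigue)
    if (is.null(ser$fatigue$time_to_fatigue))
      ser$fatigue$time_to_fatigue <- NA_real_
    ser$fatigue$time_to_fatigue <-
      as.numeric(ser$fatigue$time_to_fatigue)
  }
  if (!is.null(ser$transfer)) ser$transfer <- as.data.frame(ser$transfer)
  ser$perm_results <- lapply(ser$perm_results, function(pr) {
    pr$null_deltas <- as.numeric(pr$null_deltas)
    structure(pr, class = "perm_test")
  })
  ser$anova_tables <- lapply(ser$anova_tables, function(a) {
    structure(as.data.frame(a$table),
              class = c("mixed_anova", "data.frame"),
              epsilon = a$epsilon,
              design = unlist(a$design))
  })
  structure(ser, class = "results_bundle")
}

#' Human-readable report with permutation histograms
#'
#' Condenses a results bundle into, per comparison, the observed slope
#' difference, the p-value, and histogram bin counts of the permutation
#' null distribution (the observed difference marks the dashed-line
#' position when plotted).
#'
#' @param bundle A `results_bundle` with at least one comparison or ANOVA.
#' @param bins Number of histogram bins (default 30).
#' @return Object of class `"skill_report"`: list with `fits`,
#'   `comparisons` (each with `observed`, `p`, `breaks`, `counts`,
#'   `dashed_line`), `anova`, `provenance`.
#' @export
make_report <- function(bundle, bins = 30) {
  stopifnot(inherits(bundle, "results_bundle"))
  if (!length(bundle$perm_results) && !length(bundle$anova_tables))
    stop("empty bundle: nothing to report")
  comparisons <- lapply(bundle$perm_results, function(pr) {
    rng <- range(c(pr$null_deltas, pr$observed_delta))
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    counts <- graphics::hist(pr$null_deltas, breaks = breaks,
                             plot = FALSE)$counts
    list(observed = pr$observed_delta, p = pr$p_value,
         n_perm = pr$n_perm, breaks = breaks, counts = counts,
         dashed_line = pr$observed_delta, method = pr$method)
  })
  structure(list(fits = bundle$fits, comparisons = comparisons,
                 anova = bundle$anova_tables,
                 provenance = bundle$provenance),
            class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat("Motor-skill learning report (experiment ",
      x$provenance$experiment, ")\n", sep = "")
  if (!is.null(x$fits)) {
    cat("Learning rates (robust slope of skill on block):\n")
    print(x$fits, row.names = FALSE)
  }
  if (length(x$comparisons)) {
    cat("Comparisons (permutation tests):\n")
    for (nm in names(x$comparisons)) {
      cmp <- x$comparisons[[nm]]
      cat(sprintf("  %-28s delta = %8.4f  p = %.4g (%d resamples)\n",
                  nm, cmp$observed, cmp$p, cmp$n_perm))
    }
  }
  if (length(x$anova))
    cat("ANOVA tables:", paste(names(x$anova), collapse = ", "), "\n")
  invisible(x)
}
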