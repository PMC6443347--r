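test_that("force transduction is logarithmic, monotone and invertible", {
  expect_equal(transduce_force(0), 0)
  grid <- seq(0, 100, by = 1)
  expect_true(all(diff(transduce_force(grid, k = 2, f0 = 3)) > 0))
  for (f in c(1, 10, 40))
    expect_equal(invert_transduction(transduce_force(f, 2, 3), 2, 3), f,
                 tolerance = 1e-9)
  expect_error(transduce_force(-1), "non-negative")
})

test_that("same seed reproduces the trial table; different seeds differ", {
  cfg <- sim_config(days = 1)
  s1 <- simulate_pinch_experiment(cfg, seed = 5)
  s2 <- simulate_pinch_experiment(cfg, seed = 5)
  expect_identical(s1$trials, s2$trials)
  s3 <- simulate_pinch_experiment(cfg, seed = 6)
  expect_false(identical(s1$trials, s3$trials))
})

test_that("adding a subject never perturbs existing subjects' data", {
  g <- function(n) sim_config(groups = list(
    G = list(n_subjects = n, baseline_skill = 0.3, skill_slope = 0.1,
             fatigued_days = integer(0))), days = 1)
  small <- simulate_pinch_experiment(g(3), seed = 9)$trials
  big <- simulate_pinch_experiment(g(4), seed = 9)$trials
  expect_identical(small, big[big$subject %in% unique(small$subject), ])
})

test_that("per-block error rates match the configured probabilities", {
  # one subject, no subject/block noise, 2000 trials per block
  cfg <- sim_config(groups = list(
    G = list(n_subjects = 1, baseline_skill = 0.3, skill_slope = 0.15,
             fatigued_days = integer(0))),
    days = 1, trials_per_block = 2000, subject_sd = 0, block_sd = 0)
  sim <- simulate_pinch_experiment(cfg, seed = 17)
  bs <- summarize_blocks(sim$trials)
  for (b in 1:4) {
    p <- sim$truth$blocks$error_prob[sim$truth$blocks$block == b]
    phat <- bs$error_rate[bs$block == b]
    half <- 1.96 * sqrt(p * (1 - p) / 2000)
    expect_lt(abs(phat - p), half + 1e-12)
  }
})

test_that("noise-free, bias-free trials hit every gate", {
  # error probability driven to ~0 by a huge target skill: the calibrated
  # force noise collapses and every gate outcome is a hit
  cfg <- sim_config(groups = list(
    G = list(n_subjects = 2, baseline_skill = 5000, skill_slope = 0,
             fatigued_days = integer(0))),
    days = 1, subject_sd = 0, block_sd = 0, overshoot_beta = 0)
  sim <- simulate_pinch_experiment(cfg, seed = 3)
  expect_true(all(!sim$trials$is_error))
  expect_true(all(as.matrix(sim$trials[c("g1", "g2", "g3", "g4", "g5")])
                  == "H"))
})

test_that("movement times respect the floor and decay across blocks", {
  sim <- simulate_pinch_experiment(sim_config(days = 1), seed = 13)
  expect_true(all(sim$trials$movement_time > 1.2))
  bs <- summarize_blocks(sim$trials)
  mt_by_block <- tapply(bs$movement_time, bs$block, mean)
  expect_true(all(diff(mt_by_block) < 0))
})

test_that("skill tables carry the configured slope and noise", {
  tab <- simulate_skill_table(6, slope = 0.2, baseline = 0.4, sigma = 0,
                              seed = 1)
  expect_equal(tab$skill, 0.4 + 0.2 * tab$block)
  expect_equal(nrow(tab), 24)
  # mean slope over replicates is centred on the truth (quick check;
  # the full 200-seed study lives in the acceptance suite)
  slopes <- vapply(1:40, function(s)
    fit_learning(simulate_skill_table(10, 0.17, sigma = 0.05,
                                      seed = s))$slope, numeric(1))
  expect_lt(abs(mean(slopes) - 0.17), 0.01)
})

test_that("sim_config validates fields by name", {
  expect_error(sim_config(days = 0), "days")
  expect_error(sim_config(mt = list(start = 4.5, decay = 0.97,
                                    sdlog = 0.15, floor = 0.9)),
               "mt\\$floor")
  expect_error(sim_config(groups = list(G = list(baseline_skill = 1,
                                                 skill_slope = 0.1))),
               "n_subjects")
  expect_error(sim_config(overshoot_beta = 0.5), "overshoot_beta")
})

test_that("force-trace generator matches its exponential model", {
  tr <- simulate_force_trace(100, 0.01, 10, noise_sd = 0,
                             sampling_rate = 50)
  t <- trace_time(tr)
  expect_equal(tr$samples, 100 * exp(-0.01 * t), tolerance = 1e-12)
  flat <- simulate_force_trace(80, 0.05, 5, noise_sd = 0,
                               sampling_rate = 50, mode = "control")
  expect_equal(flat$samples, rep(4, 250))
  const <- simulate_force_trace(60, 0, 5, noise_sd = 0, sampling_rate = 50)
  expect_equal(const$samples, rep(60, 250))
  expect_error(simulate_force_trace(-5, 0.1, 10), "positive")
})

test_that("sequence generator: errorless fraction and exact times", {
  cfg0 <- sim_sequence_config(press = list(mean_start = 0.3,
                                           block_decay = 1, sdlog = 0),
                              press_error = list(start = 0,
                                                 block_decay = 1))
  tab <- simulate_sequence_experiment(cfg0, seed = 2)
  expect_true(all(tab$n_wrong_presses == 0))
  expect_equal(tab$movement_time, rep(3.0, nrow(tab)), tolerance = 1e-12)

  # errorless fraction ~ (1-p)^10 at n = 2000
  cfg <- sim_sequence_config(groups = list(G = list(n_subjects = 1)),
                             days = 1, blocks_per_day = 1,
                             trials_per_block = 2000,
                             press_error = list(start = 0.03,
                                                block_decay = 1))
  tab2 <- simulate_sequence_experiment(cfg, seed = 4)
  p_errorless <- (1 - 0.03)^10
  half <- 1.96 * sqrt(p_errorless * (1 - p_errorless) / 2000)
  expect_lt(abs(mean(tab2$n_wrong_presses == 0) - p_errorless), half)

  # declining movement times over blocks
  tab3 <- simulate_sequence_experiment(sim_sequence_config(), seed = 6)
  bs <- summarize_sequence_blocks(tab3)
  mt <- tapply(bs$movement_time, bs$block, mean)
  expect_true(all(diff(mt) < 0))
})
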