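test_that("skill score matches its closed form", {
  # ln(e) = 1 so the denominator term vanishes: (1 - 0.5)/0.5 = 1
  expect_equal(skill_measure(0.5, exp(1)), 1, tolerance = 1e-12)
  # frozen from direct high-precision evaluation of (1-ER)/(ER (ln MT)^b)
  expect_equal(skill_measure(0.2, 2.0), 0.8 / (0.2 * log(2)^5.424),
               tolerance = 1e-12)
  expect_equal(skill_measure(0.2, 2.0), 29.2026787, tolerance = 1e-7)
  # boundary adjustment keeps ER = 0 finite: ER' = 0.5/30
  er <- 0.5 / 30
  expect_equal(skill_measure(0, 2.0, n_trials = 30),
               (1 - er) / (er * log(2)^5.424), tolerance = 1e-12)
  expect_equal(skill_measure(0, 2.0, n_trials = 30), 430.73947,
               tolerance = 1e-6)
})

test_that("skill score is strictly monotone in error rate and speed", {
  ers <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(skill_measure(ers, 3)) < 0))
  mts <- seq(1.1, 10, length.out = 50)
  expect_true(all(diff(skill_measure(0.3, mts)) < 0))
})

test_that("skill score rejects out-of-domain inputs", {
  expect_error(skill_measure(0.5, 1.0), "movement_time")
  expect_error(skill_measure(0.5, 0.8), "movement_time")
  expect_error(skill_measure(-0.1, 2), "error_rate")
  expect_error(skill_measure(1.2, 2), "error_rate")
})

test_that("adjust_error_rate clamps only the boundaries", {
  expect_equal(adjust_error_rate(0, 30), 1 / 60)
  expect_equal(adjust_error_rate(1, 30), 1 - 1 / 60)
  expect_equal(adjust_error_rate(0.4, 30), 0.4)
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(adjust_error_rate(grid, 30)) >= 0))
})

test_that("summarize_blocks aggregates error rate, MT and skill", {
  miss <- c("O", "H", "H", "H", "H")
  trials <- make_trials(c(rep(list(hit5), 15), rep(list(miss), 15)),
                        mt = exp(1))
  bs <- summarize_blocks(trials)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$error_rate, 0.5)
  expect_equal(bs$skill, 1, tolerance = 1e-12)

  trials2 <- make_trials(c(rep(list(hit5), 8), rep(list(miss), 2)), mt = 2)
  bs2 <- summarize_blocks(trials2)
  expect_equal(bs2$error_rate, 0.2)
  expect_equal(bs2$skill, skill_measure(0.2, 2, n_trials = 10),
               tolerance = 1e-12)

  # error-free block uses the adjusted rate
  trials3 <- make_trials(rep(list(hit5), 30), mt = 2)
  bs3 <- summarize_blocks(trials3)
  expect_equal(bs3$error_rate, 0)
  expect_equal(bs3$skill, skill_measure(0, 2, n_trials = 30),
               tolerance = 1e-12)
})

test_that("block skill equals skill_measure of the block's own summary", {
  sim <- simulate_pinch_experiment(sim_config(days = 1), seed = 7)
  bs <- summarize_blocks(sim$trials)
  recomputed <- skill_measure(bs$error_rate, bs$movement_time,
                              n_trials = bs$n_trials)
  expect_equal(bs$skill, recomputed, tolerance = 1e-12)
  # median aggregate is exposed as an option and changes the MT column
  bs_med <- summarize_blocks(sim$trials, mt_aggregate = "median")
  expect_false(all(bs_med$movement_time == bs$movement_time))
})

test_that("summarize_blocks validates its input", {
  expect_error(summarize_blocks(data.frame()), "non-empty")
  bad <- make_trials(list(hit5))
  bad$g3 <- "X"
  expect_error(summarize_blocks(bad), "H.*O.*U|outcome")
  incons <- make_trials(list(hit5))
  incons$is_error <- TRUE
  expect_error(summarize_blocks(incons), "is_error")
})

test_that("decompose_errors matches a hand count and sums to one", {
  trials <- make_trials(list(
    c("O", "H", "H", "H", "H"),
    c("O", "U", "H", "H", "H"),
    c("H", "H", "H", "H", "U"),
    hit5))
  dec <- decompose_errors(trials)
  expect_equal(dec$overshoot_rate, c(0.5, 0, 0, 0, 0))
  expect_equal(dec$undershoot_rate, c(0, 0.25, 0, 0, 0.25))
  expect_equal(dec$hit_rate, c(0.5, 0.75, 1, 1, 0.75))
  expect_equal(dec$hit_rate + dec$overshoot_rate + dec$undershoot_rate,
               rep(1, 5))

  allhit <- decompose_errors(make_trials(rep(list(hit5), 6)))
  expect_equal(allhit$hit_rate, rep(1, 5))
})

test_that("fatigued-group errors are overshoots at the low-force gates", {
  cfg <- sim_config(days = 1)
  sim <- simulate_pinch_experiment(cfg, seed = 11)
  ftg <- sim$trials[sim$trials$group == "FTG", ]
  dec <- decompose_errors(ftg)
  low2 <- order(cfg$gates$center)[1:2]
  expect_true(all(dec$overshoot_rate[low2] > dec$undershoot_rate[low2]))
})

test_that("sequence blocks summarise errorless fraction and mean MT", {
  tab <- data.frame(subject = "s1", group = "G", day = 1, block = 1,
                    trial = 1:30, movement_time = rep(3, 30),
                    n_wrong_presses = c(rep(0, 24), rep(2, 6)))
  bs <- summarize_sequence_blocks(tab)
  expect_equal(bs$error_rate, 0.2)
  expect_equal(bs$movement_time, 3)
  tab0 <- transform(tab, n_wrong_presses = 0)
  expect_equal(summarize_sequence_blocks(tab0)$error_rate, 0)

  # brute-force recount on a random table
  set.seed(42)
  rnd <- data.frame(subject = rep(c("a", "b"), each = 30), group = "G",
                    day = 1, block = rep(1:2, 30),
                    trial = rep(1:15, 4),
                    movement_time = runif(60, 2, 5),
                    n_wrong_presses = rpois(60, 0.5))
  bs2 <- summarize_sequence_blocks(rnd)
  for (i in seq_len(nrow(bs2))) {
    sel <- rnd$subject == bs2$subject[i] & rnd$block == bs2$block[i]
    expect_equal(bs2$error_rate[i], sum(rnd$n_wrong_presses[sel] > 0) /
                   sum(sel))
    expect_equal(bs2$movement_time[i], mean(rnd$movement_time[sel]))
  }
  expect_error(summarize_sequence_blocks(data.frame()), "non-empty")
})
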