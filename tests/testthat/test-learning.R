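make_group_table <- function(series_by_subject, blocks = 1:4) {
  do.call(rbind, lapply(names(series_by_subject), function(s)
    data.frame(subject = s, block = blocks,
               skill = series_by_subject[[s]])))
}

test_that("identical subject series give their common slope", {
  tab <- make_group_table(list(s1 = c(0.1, 0.2, 0.3, 0.4),
                               s2 = c(0.1, 0.2, 0.3, 0.4),
                               s3 = c(0.1, 0.2, 0.3, 0.4)))
  fit <- fit_learning(tab)
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  flat <- make_group_table(list(s1 = rep(0.3, 4), s2 = rep(0.5, 4)))
  expect_equal(fit_learning(flat)$slope, 0, tolerance = 1e-10)
})

test_that("pooled and per-subject modes agree on homogeneous groups", {
  tab <- simulate_skill_table(8, slope = 0.2, sigma = 0.01, seed = 5)
  pooled <- fit_learning(tab)
  per <- fit_learning(tab, pooling = "per_subject")
  expect_equal(pooled$slope, per$slope, tolerance = 0.02)
  expect_length(per$subject_slopes, 8)
})

test_that("group-day slicing and fit_learning_by cover every cell", {
  sim <- simulate_pinch_experiment(sim_config(), seed = 3)
  bs <- summarize_blocks(sim$trials)
  fits <- fit_learning_by(bs)
  expect_equal(nrow(fits), 4)   # 2 groups x 2 days
  one <- fit_learning(bs, group = "FTG", day = 2)
  expect_equal(one$slope, fits$slope[fits$group == "FTG" & fits$day == 2])
  expect_equal(one$n_points, 20 * 4)
})

test_that("learning_fit methods are coherent", {
  tab <- simulate_skill_table(6, slope = 0.15, sigma = 0.03, seed = 9)
  fit <- fit_learning(tab)
  expect_equal(unname(coef(fit)[2]), fit$slope)
  expect_equal(fitted(fit) + residuals(fit), fit$skill, tolerance = 1e-12)
  expect_equal(predict(fit, newdata = c(1, 4)),
               unname(coef(fit)[1] + coef(fit)[2] * c(1, 4)))
  expect_output(print(fit), "learning rate")
  expect_output(print(summary(fit)), "residual scale")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(sort(unique(sims[[1]]$block)), sort(unique(tab$block)))
})

test_that("fit preconditions are enforced", {
  tab <- simulate_skill_table(4, slope = 0.1, seed = 2)
  expect_error(fit_learning(tab[tab$block == 1, ]), "2 distinct blocks")
  expect_error(fit_learning(tab[tab$subject == tab$subject[1], ]),
               "2 subjects")
  expect_error(fit_learning(data.frame(subject = 1, block = 1)),
               "missing column")
})

test_that("transfer delta is the block-2 minus block-1 skill difference", {
  pre <- data.frame(subject = "s1", hand = "left", block = 1, skill = 0.10)
  post <- data.frame(subject = "s1", hand = "left", block = 2, skill = 0.25)
  expect_equal(transfer_delta(pre, post), 0.15)
  expect_equal(transfer_delta(pre, pre), 0)
  expect_error(transfer_delta(pre, transform(post, subject = "s2")),
               "different subjects")
  expect_error(transfer_delta(pre, transform(post, hand = "right")),
               "different hands")
  expect_error(transfer_delta(post, pre), "precede")
})

test_that("transfer delta equals the metric difference on simulated blocks", {
  # two 15-trial blocks built at known error rates and times
  miss <- c("H", "O", "H", "H", "H")
  b1 <- make_trials(c(rep(list(hit5), 10), rep(list(miss), 5)), mt = 3,
                    block = 1)
  b2 <- make_trials(c(rep(list(hit5), 13), rep(list(miss), 2)), mt = 2.5,
                    block = 2)
  s1 <- summarize_blocks(b1)
  s2 <- summarize_blocks(b2)
  manual <- skill_measure(2 / 15, 2.5, n_trials = 15) -
    skill_measure(5 / 15, 3, n_trials = 15)
  expect_equal(transfer_delta(s1, s2), manual, tolerance = 1e-12)
})
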