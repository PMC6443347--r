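# Independent oracle implementations used to validate the package's own
# computations. These deliberately take different code paths from the
# implementation (lm()/solve() instead of the closed-form update, direct
# mean decomposition instead of aov, manual enumeration instead of the
# resampling engine).

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Full-enumeration two-group permutation p-value with plain OLS pooled
# slopes; two-sided on |delta|. Ya/Yb are subjects-by-blocks matrices.
perm_enum_oracle <- function(Ya, Yb, x) {
  slope_of <- function(Y) {
    d <- data.frame(xx = rep(x, each = nrow(Y)), yy = as.numeric(Y))
    unname(stats::coef(stats::lm(yy ~ xx, d))[2])
  }
  nA <- nrow(Ya)
  Y <- rbind(Ya, Yb)
  n <- nrow(Y)
  idx <- utils::combn(n, nA)
  deltas <- apply(idx, 2, function(ia)
    slope_of(Y[ia, , drop = FALSE]) - slope_of(Y[-ia, , drop = FALSE]))
  obs <- deltas[1]                      # first combn column is 1..nA
  list(p = mean(abs(deltas) >= abs(obs)), observed = obs, deltas = deltas)
}

# Direct mean-decomposition sums of squares for the balanced two-way
# mixed (block within-subject, group between-subject) design.
mixed_anova_oracle <- function(d) {   # columns subject, group, block, y
  m <- mean(d$y)
  k <- length(unique(d$block))
  subj_means <- tapply(d$y, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, `[`, 1)
  group_means <- tapply(d$y, d$group, mean)
  block_means <- tapply(d$y, d$block, mean)
  n_g <- table(subj_group)
  N <- length(subj_means)
  SS_group <- k * sum(n_g * (group_means[names(n_g)] - m)^2)
  SS_subj <- k * sum((subj_means - group_means[subj_group])^2)
  SS_block <- N * sum((block_means - m)^2)
  cell_means <- tapply(d$y, list(d$group, d$block), mean)
  SS_int <- 0
  for (g in rownames(cell_means)) for (b in colnames(cell_means))
    SS_int <- SS_int + n_g[[g]] *
      (cell_means[g, b] - group_means[[g]] - block_means[[b]] + m)^2
  SS_total <- sum((d$y - m)^2)
  SS_resid <- SS_total - SS_group - SS_subj - SS_block - SS_int
  G <- length(n_g)
  df <- c(group = G - 1, subj = N - G, block = k - 1,
          int = (G - 1) * (k - 1), resid = (N - G) * (k - 1))
  MS <- c(SS_group, SS_subj, SS_block, SS_int, SS_resid) / unname(df)
  list(SS = c(group = SS_group, subj = SS_subj, block = SS_block,
              int = SS_int, resid = SS_resid),
       df = df,
       F = c(group = unname(MS[1] / MS[2]), block = unname(MS[3] / MS[5]),
             int = unname(MS[4] / MS[5])))
}

# Moving-average-then-max MVC oracle (centred window, edges dropped).
mvc_oracle <- function(samples, rate, window) {
  w <- max(1, round(window * rate))
  if (w <= 1) return(max(samples))
  sm <- vapply(seq_len(length(samples) - w + 1),
               function(i) mean(samples[i:(i + w - 1)]), numeric(1))
  max(sm)
}

# A tiny hand-buildable trial table.
make_trials <- function(gates_per_trial, mt = 2.5, subject = "s1",
                        group = "G", day = 1, block = 1) {
  n <- length(gates_per_trial)
  g <- do.call(rbind, gates_per_trial)
  data.frame(subject = subject, group = group, day = day, block = block,
             trial = seq_len(n), hand = "right",
             movement_time = rep_len(mt, n),
             g1 = g[, 1], g2 = g[, 2], g3 = g[, 3], g4 = g[, 4],
             g5 = g[, 5],
             is_error = apply(g != "H", 1, any))
}

hit5 <- rep("H", 5)
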