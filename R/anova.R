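#' Mixed-design repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Two-way mixed ANOVA for the standard block-by-group design: a
#' within-subject factor (practice block, typically 4 levels) crossed with
#' a between-subject factor (group), one observation per subject per block.
#' Sums of squares, degrees of freedom and F statistics come from the
#' classical balanced decomposition (via [stats::aov()] with a subject
#' error stratum). For the within-subject effects the Greenhouse-Geisser
#' epsilon is estimated from the pooled within-group covariance matrix of
#' the repeated measures, and a sphericity-corrected p-value is reported
#' alongside the uncorrected one.
#'
#' @param data Long data frame, one row per subject-by-block cell.
#' @param dv Name of the dependent-variable column (e.g. `"movement_time"`
#'   or `"error_rate"`).
#' @param within,between,subject Names of the within-subject factor,
#'   between-subject factor and subject identifier columns. Defaults
#'   `"block"`, `"group"`, `"subject"`.
#' @return Object of class `"mixed_anova"`: a data frame of effects
#'   (`effect, SS, df, MS, F, p`) with columns `gg_epsilon` and `p_gg`
#'   filled for within-subject effects, plus attributes `epsilon` and
#'   `design`.
#' @details The design must be complete and balanced across blocks (every
#'   subject observed in every block); missing cells are an error -- no
#'   imputation is attempted. Greenhouse-Geisser epsilon for a k-level
#'   within factor is bounded in \[1/(k-1), 1\].
#' @examples
#' sim <- simulate_pinch_experiment(sim_config(days = 1), seed = 1)
#' bs <- summarize_blocks(sim$trials)
#' mixed_anova(bs, dv = "error_rate")
#' @export
mixed_anova <- function(data, dv, within = "block", between = "group",
                        subject = "subject") {
  for (col in c(dv, within, between, subject))
    if (!col %in% names(data)) stop("column '", col, "' not found in 'data'")
  d <- data.frame(y = as.numeric(data[[dv]]),
                  w = factor(data[[within]]),
                  b = factor(data[[between]]),
                  s = factor(paste(data[[between]], data[[subject]],
                                   sep = ".")))
  if (anyNA(d$y)) stop("missing values in '", dv, "' are not supported")
  counts <- table(d$s, d$w)
  if (any(counts != 1))
    stop("design must be complete and balanced: every subject needs ",
         "exactly one observation per ", within, " level (no imputation)")
  k <- nlevels(d$w)
  fit <- stats::aov(y ~ b * w + Error(s), data = d)
  sm <- summary(fit)
  btab <- as.data.frame(sm[["Error: s"]][[1]])
  wtab <- as.data.frame(sm[["Error: Within"]][[1]])
  row_of <- function(tab, pattern) tab[grep(pattern, trimws(rownames(tab))), ]
  eff <- rbind(
    data.frame(effect = "group", row_of(btab, "^b$"), row.names = NULL),
    data.frame(effect = "subjects_within_group", row_of(btab, "^Residuals$"),
               row.names = NULL),
    data.frame(effect = "block", row_of(wtab, "^w$"), row.names = NULL),
    data.frame(effect = "block:group", row_of(wtab, "^b:w$"),
               row.names = NULL),
    data.frame(effect = "within_residuals", row_of(wtab, "^Residuals$"),
               row.names = NULL))
  names(eff) <- c("effect", "df", "SS", "MS", "F", "p")
  eff <- eff[c("effect", "SS", "df", "MS", "F", "p")]
  eps <- gg_epsilon(d$y, d$w, d$b, d$s)
  eff$gg_epsilon <- NA_real_
  eff$p_gg <- NA_real_
  for (e in c("block", "block:group")) {
    i <- eff$effect == e
    df1 <- eff$df[i]
    df2 <- eff$df[eff$effect == "within_residuals"]
    eff$gg_epsilon[i] <- eps
    eff$p_gg[i] <- stats::pf(eff$F[i], eps * df1, eps * df2,
                             lower.tail = FALSE)
  }
  structure(eff, class = c("mixed_anova", "data.frame"), epsilon = eps,
            design = c(levels_within = k, n_subjects = nlevels(d$s)))
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k repeated measures: eps = tr(CSC)^2 / ((k-1) * tr((CSC)^2)), C the
# k x k centering matrix. Equals 1 under exact sphericity; lower bound
# 1/(k-1).
gg_epsilon <- function(y, w, b, s) {
  k <- nlevels(w)
  S <- matrix(0, k, k)
  dof <- 0
  for (g in levels(b)) {
    sel <- b == g
    M <- tapply(y[sel], list(droplevels(s[sel]), w[sel]), mean)
    if (nrow(M) > 1) {
      S <- S + stats::cov(M) * (nrow(M) - 1)
      dof <- dof + nrow(M) - 1
    }
  }
  S <- S / dof
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc * Sc))
  min(1, max(eps, 1 / (k - 1)))
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (within: block, between: group)\n")
  cat(sprintf("  Greenhouse-Geisser epsilon = %.4f\n", attr(x, "epsilon")))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5); df$MS <- signif(df$MS, 5)
  df$F <- signif(df$F, 5); df$p <- signif(df$p, 4)
  df$gg_epsilon <- signif(df$gg_epsilon, 4); df$p_gg <- signif(df$p_gg, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
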