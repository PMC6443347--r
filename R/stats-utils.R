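#' Two-sample Student's t-test (pooled variance)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE`, adding
#' the degenerate-sample convention used throughout the pipeline: if both
#' samples are constant with equal means the statistic is defined as t = 0
#' (p = 1); constant samples with unequal means are an error (the statistic
#' is infinite and uninformative).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero pooled variance with unequal means: t is unbounded")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Normality gate: Shapiro-Wilk screen with log-transform fallback
#'
#' Screens a sample with the Shapiro-Wilk test before parametric analysis.
#' If normality is not rejected (p >= `alpha`) the values pass through
#' unchanged; otherwise the natural-log-transformed values are returned
#' and flagged, mirroring the common workflow of log-transforming skewed
#' positive behavioural measures.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Rejection level for the W test; default 0.05.
#' @return List with `values` (possibly transformed), `transformed`
#'   (logical), and `shapiro_p` (the p-value of the original sample).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("at least 3 values are required")
  p <- stats::shapiro.test(values)$p.value
  if (p >= alpha)
    return(list(values = values, transformed = FALSE, shapiro_p = p))
  if (any(values <= 0))
    stop("log-transform required (Shapiro-Wilk p < ", alpha,
         ") but values are not all positive")
  list(values = log(values), transformed = TRUE, shapiro_p = p)
}

#' Bonferroni adjustment
#'
#' Adjusted p-values `min(1, m * p)`. With the default `m` this is
#' identical to `stats::p.adjust(p, "bonferroni")`; `m` can be set larger
#' when the family includes comparisons not in `p_values`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (m == length(p_values)) return(stats::p.adjust(p_values, "bonferroni"))
  pmin(1, m * p_values)
}
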