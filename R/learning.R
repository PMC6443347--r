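#' Fit a group learning curve: robust regression of skill on block
#'
#' The central estimator of the package. For one group (and one day), the
#' per-subject, per-block skill scores are regressed on the block number
#' (1-4) by robust IRLS regression ([irls_fit()]); the slope is the group's
#' learning rate for that day. By default all subject-by-block points of
#' the group are pooled into a single regression; alternatively a robust
#' line can be fitted per subject and the coefficients averaged
#' (`pooling = "per_subject"`, a sensitivity analysis).
#'
#' @param data Data frame of block summaries with at least columns
#'   `subject`, `block`, `skill` (as produced by [summarize_blocks()] or
#'   [simulate_skill_table()]); may also carry `group` and `day` columns.
#' @param group,day Optional value used to slice `data` before fitting
#'   (and recorded in the result).
#' @param pooling `"pooled"` (one regression over all points, default) or
#'   `"per_subject"` (average of per-subject robust slopes).
#' @param psi,tuning,tol,max_iter Passed to [irls_fit()].
#' @return Object of class `"learning_fit"` with components
#'   `coefficients` (intercept, slope), `slope` (the learning rate),
#'   `weights`, `n_points`, `n_subjects`, `iterations`, `converged`,
#'   `group`, `day`, `pooling`, `psi`, and the fitted points
#'   (`block`, `skill`, `subject`). Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `fitted`, `plot`, `simulate`.
#' @examples
#' tab <- simulate_skill_table(n_subjects = 12, slope = 0.17, seed = 1)
#' fit <- fit_learning(tab)
#' coef(fit)
#' @export
fit_learning <- function(data, group = NULL, day = NULL,
                         pooling = c("pooled", "per_subject"),
                         psi = c("bisquare", "huber", "none"), tuning = NULL,
                         tol = 1e-8, max_iter = 100L) {
  pooling <- match.arg(pooling)
  psi <- match.arg(psi)
  if (!is.null(group) && "group" %in% names(data))
    data <- data[data$group == group, , drop = FALSE]
  if (!is.null(day) && "day" %in% names(data))
    data <- data[data$day == day, , drop = FALSE]
  need <- c("subject", "block", "skill")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("'data' is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(data) == 0) stop("no rows to fit (empty group/day slice)")
  if (length(unique(data$block)) < 2)
    stop("at least 2 distinct blocks are required to estimate a slope")
  subjects <- unique(data$subject)
  if (length(subjects) < 2)
    stop("at least 2 subjects are required for a group fit")
  x <- as.numeric(data$block)
  y <- as.numeric(data$skill)
  if (pooling == "pooled") {
    core <- irls_core(x, y, psi,
                      if (is.null(tuning))
                        switch(psi, bisquare = 4.685, huber = 1.345, none = Inf)
                      else tuning,
                      tol, max_iter)
    coefs <- core$coefficients
    weights <- core$weights
    iterations <- core$iterations
    converged <- core$converged
    subject_slopes <- NULL
  } else {
    fits <- lapply(split(seq_len(nrow(data)), data$subject), function(i) {
      irls_fit(x[i], y[i], psi = psi, tuning = tuning, tol = tol,
               max_iter = max_iter)
    })
    cf <- vapply(fits, coef, numeric(2))
    coefs <- c(intercept = mean(cf[1, ]), slope = mean(cf[2, ]))
    weights <- unlist(lapply(fits, `[[`, "weights"), use.names = FALSE)
    iterations <- max(vapply(fits, `[[`, integer(1), "iterations"))
    converged <- all(vapply(fits, `[[`, logical(1), "converged"))
    subject_slopes <- cf[2, ]
  }
  structure(list(coefficients = coefs, slope = unname(coefs[2]),
                 weights = weights, n_points = length(x),
                 n_subjects = length(subjects), iterations = iterations,
                 converged = converged, group = group, day = day,
                 pooling = pooling, psi = psi,
                 subject_slopes = subject_slopes,
                 block = x, skill = y, subject = data$subject),
            class = "learning_fit")
}

#' Fit learning curves for every group-day combination
#'
#' Convenience wrapper applying [fit_learning()] to each group-day slice of
#' a block-summary table.
#'
#' @param data Block summaries with `group` and `day` columns.
#' @param ... Passed to [fit_learning()].
#' @return Data frame with one row per group-day
#'   (`group, day, slope, intercept, n_points, converged`) and the fits in
#'   attribute `"fits"`.
#' @export
fit_learning_by <- function(data, ...) {
  if (!all(c("group", "day") %in% names(data)))
    stop("'data' must have 'group' and 'day' columns")
  combos <- unique(data[c("group", "day")])
  combos <- combos[order(combos$group, combos$day), , drop = FALSE]
  fits <- lapply(seq_len(nrow(combos)), function(i) {
    fit_learning(data, group = combos$group[i], day = combos$day[i], ...)
  })
  out <- data.frame(group = combos$group, day = combos$day,
                    slope = vapply(fits, `[[`, numeric(1), "slope"),
                    intercept = vapply(fits, function(f)
                      unname(f$coefficients[1]), numeric(1)),
                    n_points = vapply(fits, `[[`, integer(1), "n_points"),
                    converged = vapply(fits, `[[`, logical(1), "converged"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Two-block learning measure for transfer blocks
#'
#' When only two blocks exist (e.g. the untrained hand tested once before
#' and once after training), learning is measured as the skill difference
#' block 2 minus block 1 for each subject.
#'
#' @param pre,post Single-row block summaries (or lists) with fields
#'   `subject`, `hand`, `skill`; `pre` must precede `post`.
#' @return Numeric skill difference `post$skill - pre$skill`.
#' @export
transfer_delta <- function(pre, post) {
  for (f in c("subject", "skill")) {
    if (is.null(pre[[f]]) || is.null(post[[f]]))
      stop("'pre' and 'post' must both carry '", f, "'")
  }
  if (!identical(as.character(pre$subject), as.character(post$subject)))
    stop("'pre' and 'post' belong to different subjects")
  if (!is.null(pre$hand) && !is.null(post$hand) &&
      !identical(as.character(pre$hand), as.character(post$hand)))
    stop("'pre' and 'post' were measured on different hands")
  if (!is.null(pre$block) && !is.null(post$block) &&
      !all(as.numeric(post$block) >= as.numeric(pre$block)))
    stop("'pre' must precede 'post'")
  as.numeric(post$skill) - as.numeric(pre$skill)
}

#' @export
print.learning_fit <- function(x, ...) {
  hdr <- "Group learning fit (robust regression of skill on block)"
  cat(hdr, "\n", sep = "")
  if (!is.null(x$group) || !is.null(x$day))
    cat("  group: ", x$group %||% "-", "   day: ", x$day %||% "-", "\n",
        sep = "")
  cat(sprintf("  learning rate (slope): %.4f   intercept: %.4f\n",
              x$coefficients[2], x$coefficients[1]))
  cat(sprintf("  %d points (%d subjects), pooling = %s, psi = %s\n",
              x$n_points, x$n_subjects, x$pooling, x$psi))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.learning_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 residual_scale = stats::median(abs(r)) / 0.6745,
                 weight_summary = summary(object$weights),
                 downweighted = sum(object$weights < 0.5)),
            class = "summary.learning_fit")
}

#' @export
print.summary.learning_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  robust residual scale: %.4g\n", x$residual_scale))
  cat(sprintf("  points with weight < 0.5: %d\n", x$downweighted))
  invisible(x)
}

#' @export
coef.learning_fit <- function(object, ...) object$coefficients

#' @export
fitted.learning_fit <- function(object, ...) {
  object$coefficients[1] + object$coefficients[2] * object$block
}

#' @export
residuals.learning_fit <- function(object, ...) {
  object$skill - fitted(object)
}

#' @rdname fit_learning
#' @param object,x A `learning_fit`.
#' @param newdata Optional data frame (or vector) of block numbers to
#'   predict at; defaults to the fitted blocks.
#' @export
predict.learning_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  blocks <- if (is.data.frame(newdata)) newdata$block else newdata
  object$coefficients[1] + object$coefficients[2] * as.numeric(blocks)
}

#' @rdname fit_learning
#' @param nsim,seed Number of simulated skill tables and RNG seed.
#' @export
simulate.learning_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- residuals(object)
  sigma <- stats::median(abs(r)) / 0.6745
  blocks <- sort(unique(object$block))
  lapply(seq_len(nsim), function(i) {
    simulate_skill_table(n_subjects = object$n_subjects,
                         slope = object$coefficients[2],
                         baseline = object$coefficients[1],
                         sigma = sigma, blocks = blocks,
                         seed = sample.int(.Machine$integer.max - 1, 1))
  })
}

#' @rdname fit_learning
#' @export
plot.learning_fit <- function(x, ...) {
  graphics::plot(jitter(x$block, 0.15), x$skill, xlab = "block",
                 ylab = "skill", pch = 16,
                 col = grDevices::grey(1 - 0.8 * x$weights), ...)
  graphics::abline(x$coefficients[1], x$coefficients[2], lwd = 2)
  invisible(x)
}
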