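# Quantification of maximal voluntary contraction (MVC) and muscle fatigue
# from pinch-force transducer traces.

#' Construct a force trace
#'
#' A regularly sampled pinch-force recording in Newton.
#'
#' @param samples Numeric vector of non-negative forces (N).
#' @param sampling_rate Samples per second (Hz).
#' @return Object of class `"force_trace"` with fields `samples`,
#'   `sampling_rate`, `duration` (seconds), and a `time()`-like vector via
#'   `trace_time()`.
#' @export
force_trace <- function(samples, sampling_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("'samples' must be non-empty")
  if (any(!is.finite(samples)) || any(samples < 0))
    stop("forces must be finite and non-negative")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be positive")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 duration = length(samples) / sampling_rate),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %.2f s at %g Hz (%d samples), peak %.1f N\n",
              x$duration, x$sampling_rate, length(x$samples),
              max(x$samples)))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, ...) {
  graphics::plot(trace_time(x), x$samples, type = "l", xlab = "time (s)",
                 ylab = "force (N)", ...)
  invisible(x)
}

#' Sample times of a force trace
#' @param trace A [force_trace()].
#' @return Numeric vector of sample times in seconds (starting at 0).
#' @export
trace_time <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

# Centered moving average; partial windows at the edges are dropped (NA).
smooth_trace <- function(trace, smoothing_window) {
  w <- max(1L, round(smoothing_window * trace$sampling_rate))
  if (w <= 1) return(trace$samples)
  as.numeric(stats::filter(trace$samples, rep(1 / w, w), sides = 2))
}

#' Maximal voluntary contraction from a force trace
#'
#' The MVC is read off a short (typically 5 s) maximal-effort recording as
#' the maximum of the moving-average-smoothed trace; smoothing rejects
#' transducer noise spikes that would otherwise inflate the maximum.
#'
#' @param trace A [force_trace()].
#' @param smoothing_window Width of the centred moving average in seconds
#'   (default 0.2 s; 0 disables smoothing).
#' @return MVC in Newton.
#' @export
mvc_from_trace <- function(trace, smoothing_window = 0.2) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$duration < smoothing_window)
    stop("trace shorter than the smoothing window")
  max(smooth_trace(trace, smoothing_window), na.rm = TRUE)
}

#' Threshold force of the strongest gate
#'
#' The fatigue-induction stopping rule is tied to the upper force limit of
#' the gate requiring the largest force production (at most 40\% of MVC, so
#' that even a fatigued subject can still execute the task). Given the MVC
#' and the gate windows' upper limits as fractions of MVC, returns that
#' threshold in Newton.
#'
#' @param mvc MVC in Newton (> 0).
#' @param gate_upper_fractions Upper window limits of the scored gates as
#'   fractions of MVC, each in (0, 0.4\]. Default [default_gate_windows()].
#' @return Threshold force in Newton (`mvc * max(gate_upper_fractions)`).
#' @export
gate2_threshold <- function(mvc, gate_upper_fractions =
                              default_gate_windows()$upper) {
  if (!is.finite(mvc) || mvc <= 0) stop("'mvc' must be positive")
  if (any(gate_upper_fractions <= 0 | gate_upper_fractions > 0.4))
    stop("gate window fractions must lie in (0, 0.4]")
  mvc * max(gate_upper_fractions)
}

#' Time to fatigue: sustained threshold crossing of a force trace
#'
#' During sustained maximal contraction, the time to fatigue is the first
#' moment at which the (smoothed) force drops below the threshold and
#' stays below it for at least `hold` seconds; brief dips shorter than the
#' hold are ignored as noise. Returns `NA` if the trace never satisfies
#' the rule ("not reached").
#'
#' @param trace A [force_trace()]; must start above the threshold.
#' @param threshold_force Threshold in Newton (e.g. [gate2_threshold()]).
#' @param hold Minimum sub-threshold dwell time in seconds (default 0.5).
#' @param smoothing_window Moving-average width in seconds (default 0.2).
#' @return Crossing time in seconds, or `NA_real_` if never reached.
#' @export
time_to_fatigue <- function(trace, threshold_force, hold = 0.5,
                            smoothing_window = 0.2) {
  stopifnot(inherits(trace, "force_trace"))
  sm <- smooth_trace(trace, smoothing_window)
  ok <- which(!is.na(sm))
  if (!length(ok)) stop("trace too short to smooth")
  if (sm[ok[1]] <= threshold_force)
    stop("trace does not start above the threshold force")
  below <- sm[ok] < threshold_force
  need <- max(1L, ceiling(hold * trace$sampling_rate))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= need)
  if (!length(hit)) return(NA_real_)
  (ok[starts[hit[1]]] - 1) / trace$sampling_rate
}

#' Fractional MVC decrement
#'
#' `1 - mvc_post / mvc_pre`: the fraction of maximal force lost between
#' the pre- and post-session MVC assessments (about 0.6 after a successful
#' fatigue induction).
#'
#' @param mvc_pre,mvc_post MVC in Newton; `mvc_pre > 0`, both non-negative.
#' @return Decrement fraction.
#' @export
fatigue_decrement <- function(mvc_pre, mvc_post) {
  if (any(mvc_pre <= 0)) stop("'mvc_pre' must be positive")
  if (any(mvc_post < 0)) stop("forces must be non-negative")
  1 - mvc_post / mvc_pre
}

#' Per-session fatigue summary
#'
#' Bundles the pre/post MVC values, the decrement fraction, the gate-2
#' threshold force and the time to fatigue into one record.
#'
#' @param mvc_pre,mvc_post MVC in Newton.
#' @param threshold_force Threshold in Newton (defaults to
#'   [gate2_threshold()] of `mvc_pre`).
#' @param time_to_fatigue Crossing time in seconds or `NA`.
#' @return Object of class `"fatigue_summary"`.
#' @export
fatigue_summary <- function(mvc_pre, mvc_post,
                            threshold_force = gate2_threshold(mvc_pre),
                            time_to_fatigue = NA_real_) {
  if (threshold_force >= mvc_pre)
    stop("'threshold_force' must be below 'mvc_pre'")
  structure(list(mvc_pre = mvc_pre, mvc_post = mvc_post,
                 decrement_fraction = fatigue_decrement(mvc_pre, mvc_post),
                 threshold_force = threshold_force,
                 time_to_fatigue = time_to_fatigue),
            class = "fatigue_summary")
}

#' @export
print.fatigue_summary <- function(x, ...) {
  cat(sprintf("MVC pre %.1f N -> post %.1f N (decrement %.1f%%)\n",
              x$mvc_pre, x$mvc_post, 100 * x$decrement_fraction))
  cat(sprintf("threshold %.1f N, time to fatigue %s\n", x$threshold_force,
              if (is.na(x$time_to_fatigue)) "not reached"
              else sprintf("%.1f s", x$time_to_fatigue)))
  invisible(x)
}
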