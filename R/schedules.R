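#' Switching schedules
#'
#' A schedule maps the fraction of elapsed switching time to the coupling
#' parameter \eqn{\lambda} as a piecewise-linear path from (0, 0) to (1, 1).
#' The standard linear protocol increments \eqn{\lambda} uniformly,
#' \eqn{\lambda_i = i/N_{switch}}; stepwise-linear protocols switch faster in
#' an initial stage (crossing the fast solvent-reorientation timescale
#' quickly) and slower afterwards.
#'
#' @param breakpoints Data frame or 2-column matrix with columns
#'   `time_frac` and `lambda`, both non-decreasing from (0, 0) to (1, 1).
#' @param label Schedule identifier.
#' @return An object of class `schedule`.
#' @export
schedule <- function(breakpoints, label = "custom") {
  bp <- as.data.frame(breakpoints)
  names(bp) <- c("time_frac", "lambda")
  if (nrow(bp) < 2L)
    stopf("schedule error: need at least the two endpoints")
  if (abs(bp$time_frac[1]) > 1e-12 || abs(bp$lambda[1]) > 1e-12 ||
      abs(bp$time_frac[nrow(bp)] - 1) > 1e-12 ||
      abs(bp$lambda[nrow(bp)] - 1) > 1e-12)
    stopf("schedule error: breakpoints must run from (0, 0) to (1, 1)")
  if (is.unsorted(bp$time_frac) || is.unsorted(bp$lambda))
    stopf("schedule error: both coordinates must be non-decreasing")
  structure(list(breakpoints = bp, label = label), class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("<schedule %s> breakpoints:\n", x$label))
  print(x$breakpoints, row.names = FALSE)
  invisible(x)
}

#' Standard linear switching schedule
#'
#' \eqn{\lambda} at step i equals \eqn{i/N_{switch}}.
#'
#' @param n_switch_steps Number of switching steps (>= 1); recorded as an
#'   attribute, the path itself is the straight line from (0,0) to (1,1).
#' @return A `schedule` labelled `"L1"`.
#' @export
linear_schedule <- function(n_switch_steps = 2000) {
  check_count(n_switch_steps, "n_switch_steps", min = 1L)
  out <- schedule(data.frame(time_frac = c(0, 1), lambda = c(0, 1)),
                  label = "L1")
  attr(out, "n_switch_steps") <- as.integer(n_switch_steps)
  out
}

#' Stepwise-linear switching schedule
#'
#' Builds a piecewise-linear \eqn{\lambda(t)} from stage durations and stage
#' end values.  The shipped presets (see [schedule_preset()]) switch from 0
#' to 0.35 in the first 200 fs of a 2000 fs path and spend the remaining time
#' on the slower approach to 1.
#'
#' @param stages Data frame (or list of 2-vectors) with columns
#'   `duration_fs` and `lambda_end`; durations must sum to `total_fs`,
#'   `lambda_end` must be non-decreasing and end at 1.
#' @param total_fs Total switching length in fs.
#' @param label Schedule identifier.
#' @return A `schedule`.
#' @examples
#' s <- stepwise_schedule(data.frame(duration_fs = c(200, 1800),
#'                                   lambda_end = c(0.35, 1)), 2000)
#' @export
stepwise_schedule <- function(stages, total_fs, label = "custom") {
  if (!is.data.frame(stages))
    stages <- as.data.frame(do.call(rbind, stages))
  names(stages) <- c("duration_fs", "lambda_end")
  if (abs(sum(stages$duration_fs) - total_fs) > 1e-9)
    stopf("schedule error: stage durations sum to %g fs, not total_fs = %g fs",
          sum(stages$duration_fs), total_fs)
  if (is.unsorted(stages$lambda_end))
    stopf("schedule error: `lambda_end` values must be non-decreasing")
  if (abs(stages$lambda_end[nrow(stages)] - 1) > 1e-12)
    stopf("schedule error: final `lambda_end` must be 1.0")
  bp <- data.frame(time_frac = c(0, cumsum(stages$duration_fs) / total_fs),
                   lambda = c(0, stages$lambda_end))
  schedule(bp, label = label)
}

#' Preset switching protocols
#'
#' The four shipped protocols over a common total switching length:
#' * `L1`: standard linear.
#' * `L2-1`: 0 to 0.35 in 200 fs, then to 1.0 over 1800 fs.
#' * `L3-1`: 0 to 0.35 to 0.8 to 1.0 over 200, 900 and 900 fs.
#' * `L3-2`: 0 to 0.35 to 0.8 to 1.0 over 200, 400 and 1400 fs.
#'
#' Stage durations scale proportionally if `total_fs` differs from the
#' 2000 fs the presets are defined at.
#'
#' @param label One of `"L1"`, `"L2-1"`, `"L3-1"`, `"L3-2"`.
#' @param total_fs Total switching length (fs).
#' @return A `schedule`.
#' @examples
#' lambda_at(schedule_preset("L2-1"), 200, 2000)  # 0.35
#' @export
schedule_preset <- function(label, total_fs = 2000) {
  scale <- total_fs / 2000
  switch(label,
    "L1" = linear_schedule(as.integer(total_fs)),
    "L2-1" = stepwise_schedule(
      data.frame(duration_fs = c(200, 1800) * scale,
                 lambda_end = c(0.35, 1.0)), total_fs, label = "L2-1"),
    "L3-1" = stepwise_schedule(
      data.frame(duration_fs = c(200, 900, 900) * scale,
                 lambda_end = c(0.35, 0.8, 1.0)), total_fs, label = "L3-1"),
    "L3-2" = stepwise_schedule(
      data.frame(duration_fs = c(200, 400, 1400) * scale,
                 lambda_end = c(0.35, 0.8, 1.0)), total_fs, label = "L3-2"),
    stopf("validation error: unknown schedule label '%s'", label)
  )
}

#' Coupling value at a given switching step
#'
#' Piecewise-linear interpolation of the schedule's breakpoints in continuous
#' time, evaluated at integer step times (breakpoints need not align with
#' steps); exactly the breakpoint value at a breakpoint.
#'
#' @param sched A `schedule`.
#' @param step Step index, `0 <= step <= n_switch_steps` (vectorized).
#' @param n_switch_steps Total number of switching steps.
#' @return \eqn{\lambda} value(s) in `[0, 1]`.
#' @examples
#' lambda_at(linear_schedule(2000), 1000, 2000)  # 0.5
#' @export
lambda_at <- function(sched, step, n_switch_steps) {
  stopifnot(inherits(sched, "schedule"))
  check_count(n_switch_steps, "n_switch_steps", min = 1L)
  if (any(step < 0 | step > n_switch_steps))
    stopf("index error: `step` must lie in [0, %d]", n_switch_steps)
  bp <- sched$breakpoints
  approx(bp$time_frac, bp$lambda, xout = step / n_switch_steps,
         method = "linear", ties = "ordered")$y
}

# full lambda path lambda_0 .. lambda_N (internal)
lambda_path <- function(sched, n_switch_steps) {
  lambda_at(sched, 0:n_switch_steps, n_switch_steps)
}
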