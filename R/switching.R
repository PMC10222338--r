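#' Switch settings
#'
#' @param n_switch_steps Number of switching steps \eqn{N_{switch}} (>= 1).
#' @param timestep Timestep \eqn{\delta t} in fs.
#' @param schedule A [schedule()]; defaults to the linear protocol.
#' @param direction `"forward"` (low to high) or `"backward"` (high to low;
#'   the roles of the two levels are swapped and \eqn{\lambda} is measured
#'   toward the target level).
#' @param seed Master seed; switch i uses `child_seed(seed, "switch", i)`.
#' @param friction Optional Langevin friction (1/ps) override; the
#'   thermostat stays active during switches.
#' @return An object of class `switch_settings`.
#' @export
switch_settings <- function(n_switch_steps = 2000, timestep = 1,
                            schedule = NULL, direction = c("forward", "backward"),
                            seed = 1, friction = NULL) {
  check_count(n_switch_steps, "n_switch_steps", min = 1L)
  check_number(timestep, "timestep", positive = TRUE)
  direction <- match.arg(direction)
  if (is.null(schedule)) schedule <- linear_schedule(n_switch_steps)
  stopifnot(inherits(schedule, "schedule"))
  check_number(seed, "seed", nonneg = TRUE)
  structure(
    list(n_switch_steps = as.integer(n_switch_steps), timestep = timestep,
         schedule = schedule, direction = direction, seed = seed,
         friction = friction),
    class = "switch_settings"
  )
}

# run the engine for a set of starts; system must already be oriented in the
# direction of travel (low = initial level)
run_switch_engine <- function(system, starts, settings, keep_trace = FALSE) {
  lambdas <- lambda_path(settings$schedule, settings$n_switch_steps)
  es <- engine_sys(system, dt = settings$timestep, friction = settings$friction)
  n <- length(starts)
  seeds <- vapply(seq_len(n), function(i) child_seed(settings$seed, "switch", i), 0)
  if (starts$kind == "harmonic") {
    harm_switch_cpp(es, starts$data$x, starts$data$v, lambdas, seeds, keep_trace)
  } else {
    bath_switch_cpp(es, starts$data$orientations, starts$data$angvel,
                    lambdas, seeds, keep_trace)
  }
}

#' Run an ensemble of non-equilibrium switches
#'
#' Propagates Langevin dynamics on the hybrid potential \eqn{U(\lambda_t)}
#' from each starting configuration while the schedule drives \eqn{\lambda}
#' from 0 to 1; after each dynamics step the work increment
#' \eqn{U(x_{t+\delta t}, \lambda_{t+\delta t}) - U(x_{t+\delta t},
#' \lambda_t)} is accumulated (both energies at the post-step coordinates).
#' Switches are independent: each has its own child seed, so results do not
#' depend on execution order.  Velocities are taken from the saved restart
#' records, not resampled.
#'
#' @param system A `dual_level_system`.
#' @param starts A `restart_pool` of starting configurations.  For
#'   `direction = "backward"` the pool must have been sampled at the high
#'   level; the schedule then drives the system toward the low level and the
#'   reported work is for the high-to-low transformation.
#' @param settings A [switch_settings()].
#' @return A data frame of class `work_table` with one row per switch:
#'   `switch_id`, `direction`, `schedule`, `n_steps`,
#'   `final_work_kcal_mol`, `start_replicate`, `start_step`, `seed`.
#' @export
run_switch_ensemble <- function(system, starts, settings) {
  stopifnot(inherits(system, "dual_level_system"),
            inherits(starts, "restart_pool"),
            inherits(settings, "switch_settings"))
  if (length(starts) == 0L)
    stopf("estimation error: empty start pool")
  sys_run <- if (settings$direction == "backward") reverse_system(system) else system
  res <- run_switch_engine(sys_run, starts, settings)
  n <- length(starts)
  out <- data.frame(
    switch_id = seq_len(n),
    direction = settings$direction,
    schedule = settings$schedule$label,
    n_steps = settings$n_switch_steps,
    final_work_kcal_mol = res$work,
    start_replicate = starts$replicate,
    start_step = starts$step,
    seed = vapply(seq_len(n), function(i) child_seed(settings$seed, "switch", i), 0)
  )
  class(out) <- c("work_table", "data.frame")
  attr(out, "beta") <- system$thermo$beta
  out
}

#' Run a single non-equilibrium switch
#'
#' Single-switch variant of [run_switch_ensemble()] that also returns the
#' cumulative work trace and the final configuration.
#'
#' @param system A `dual_level_system`.
#' @param start A configuration: for a harmonic pair a list with `x` and `v`
#'   (as from [pool_config()]); for a dipole bath a [bath_configuration()].
#' @param settings A [switch_settings()].
#' @return An object of class `work_record` with fields `final_work`
#'   (kcal/mol), `work_trace` (length `n_switch_steps + 1`, starts at 0),
#'   `final_config`, `start_provenance`, `schedule_label` and `direction`.
#' @export
run_switch <- function(system, start, settings) {
  stopifnot(inherits(system, "dual_level_system"),
            inherits(settings, "switch_settings"))
  sys_run <- if (settings$direction == "backward") reverse_system(system) else system
  if (sys_run$kind == "harmonic") {
    starts <- new_restart_pool("harmonic", 0,
                               list(x = start$x, v = start$v),
                               replicate = start$replicate %||% NA_integer_,
                               step = start$step %||% NA_integer_,
                               time_fs = start$time_fs %||% 0,
                               settings = NULL, source_label = "manual")
  } else {
    u <- array(start$orientations, dim = c(3, ncol(start$orientations), 1))
    w <- array(start$angvel, dim = dim(u))
    starts <- new_restart_pool("bath", 0, list(orientations = u, angvel = w),
                               replicate = start$replicate %||% NA_integer_,
                               step = start$step %||% NA_integer_,
                               time_fs = start$time_fs %||% 0,
                               settings = NULL, source_label = "manual",
                               n_sites = ncol(start$orientations))
  }
  res <- run_switch_engine(sys_run, starts, settings, keep_trace = TRUE)
  final_config <- if (sys_run$kind == "harmonic") {
    list(x = res$x[1], v = res$v[1])
  } else {
    bath_configuration(res$orientations[, , 1], angvel = res$angvel[, , 1])
  }
  structure(
    list(final_work = res$work[1], work_trace = res$trace[, 1],
         final_config = final_config,
         start_provenance = list(replicate = starts$replicate,
                                 step = starts$step),
         schedule_label = settings$schedule$label,
         direction = settings$direction),
    class = "work_record"
  )
}

#' @export
print.work_record <- function(x, ...) {
  cat(sprintf("<work_record> W = %.6g kcal/mol (%s, schedule %s)\n",
              x$final_work, x$direction, x$schedule_label))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
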