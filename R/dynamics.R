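#' Sampler settings for equilibrium Langevin dynamics
#'
#' @param timestep Integration timestep (fs).
#' @param friction Optional Langevin friction (1/ps) overriding the system's
#'   own value.
#' @param n_equil_steps Steps discarded as equilibration per replicate.
#' @param n_prod_steps Production steps per replicate.
#' @param save_every Save a restart configuration every this many steps.
#' @param n_replicates Number of independent replicate trajectories, each
#'   initialized with different Maxwell-Boltzmann velocities.
#' @param seed Master seed; replicate r uses `child_seed(seed, tag, r)`.
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(timestep = 1, friction = NULL,
                             n_equil_steps = 1000, n_prod_steps = 10000,
                             save_every = 100, n_replicates = 8, seed = 1) {
  check_number(timestep, "timestep", positive = TRUE)
  if (!is.null(friction)) check_number(friction, "friction", positive = TRUE)
  check_count(n_equil_steps, "n_equil_steps")
  check_count(n_prod_steps, "n_prod_steps")
  check_count(save_every, "save_every", min = 1L)
  check_count(n_replicates, "n_replicates", min = 1L)
  check_number(seed, "seed", nonneg = TRUE)
  structure(
    list(timestep = timestep, friction = friction,
         n_equil_steps = as.integer(n_equil_steps),
         n_prod_steps = as.integer(n_prod_steps),
         save_every = as.integer(save_every),
         n_replicates = as.integer(n_replicates), seed = seed),
    class = "sampler_settings"
  )
}

new_restart_pool <- function(kind, lambda, data, replicate, step, time_fs,
                             settings, source_label, n_sites = 0L,
                             sites = NULL, u_low = NULL, u_high = NULL) {
  structure(
    list(kind = kind, lambda = lambda, data = data,
         replicate = as.integer(replicate), step = as.integer(step),
         time_fs = time_fs, settings = settings, source_label = source_label,
         n_sites = n_sites, sites = sites, u_low = u_low, u_high = u_high),
    class = "restart_pool"
  )
}

#' @export
length.restart_pool <- function(x) length(x$replicate)

#' @export
`[.restart_pool` <- function(x, i) {
  i <- seq_len(length(x))[i]
  out <- x
  if (x$kind == "harmonic") {
    out$data <- list(x = x$data$x[i], v = x$data$v[i])
  } else {
    out$data <- list(orientations = x$data$orientations[, , i, drop = FALSE],
                     angvel = x$data$angvel[, , i, drop = FALSE])
  }
  out$replicate <- x$replicate[i]
  out$step <- x$step[i]
  out$time_fs <- x$time_fs[i]
  if (!is.null(x$u_low)) out$u_low <- x$u_low[i]
  if (!is.null(x$u_high)) out$u_high <- x$u_high[i]
  out
}

#' @export
print.restart_pool <- function(x, ...) {
  cat(sprintf("<restart_pool> %d configurations (%s system), lambda = %g, %d replicate(s)\n",
              length(x), x$kind, x$lambda, length(unique(x$replicate))))
  invisible(x)
}

#' Extract one configuration from a restart pool
#'
#' @param pool A [restart_pool][sample_equilibrium()].
#' @param i Index.
#' @return For a dipole-bath pool a [bath_configuration()]; for a harmonic
#'   pool a list with `x` and `v`.
#' @export
pool_config <- function(pool, i) {
  stopifnot(inherits(pool, "restart_pool"))
  i <- check_count(i, "i", min = 1L)
  if (i > length(pool)) stopf("index error: pool has %d configurations", length(pool))
  if (pool$kind == "harmonic") {
    list(x = pool$data$x[i], v = pool$data$v[i], time_fs = pool$time_fs[i],
         replicate = pool$replicate[i], step = pool$step[i])
  } else {
    bath_configuration(pool$data$orientations[, , i],
                       angvel = pool$data$angvel[, , i],
                       time_fs = pool$time_fs[i],
                       replicate = pool$replicate[i], step = pool$step[i])
  }
}

#' Equilibrium sampling at fixed coupling
#'
#' Runs `n_replicates` independent Langevin trajectories on the hybrid
#' potential \eqn{U(\lambda)}, discards the equilibration phase, and saves a
#' restart configuration (coordinates and velocities) every `save_every`
#' steps.  Velocities are drawn from Maxwell-Boltzmann at the stated
#' temperature per replicate, seeded deterministically from
#' `(seed, replicate)` so that identical seeds give bit-identical pools.
#'
#' @param system A `dual_level_system`.
#' @param lambda_value Coupling parameter in `[0, 1]`.
#' @param settings A [sampler_settings()].
#' @return A `restart_pool` with per-configuration provenance (replicate and
#'   step) and the per-frame energies of both levels.
#' @export
sample_equilibrium <- function(system, lambda_value, settings) {
  stopifnot(inherits(system, "dual_level_system"),
            inherits(settings, "sampler_settings"))
  check_fraction(lambda_value, "lambda_value")
  es <- engine_sys(system, dt = settings$timestep, friction = settings$friction)
  n_save <- settings$n_prod_steps %/% settings$save_every
  steps <- rep(seq_len(max(n_save, 0)) * settings$save_every,
               times = settings$n_replicates)
  reps <- rep(seq_len(settings$n_replicates), each = max(n_save, 0))

  if (system$kind == "harmonic") {
    xs <- vs <- ul <- uh <- numeric(0)
    for (r in seq_len(settings$n_replicates)) {
      s <- child_seed(settings$seed, "equilibrate", r)
      res <- harm_sample_cpp(es, lambda_value, settings$n_equil_steps,
                             settings$n_prod_steps, settings$save_every,
                             x_init = (1 - lambda_value) * system$x0_low +
                               lambda_value * system$x0_high,
                             seed = s)
      xs <- c(xs, res$x); vs <- c(vs, res$v)
      ul <- c(ul, res$u_low); uh <- c(uh, res$u_high)
    }
    new_restart_pool("harmonic", lambda_value, list(x = xs, v = vs),
                     reps, steps, steps * settings$timestep, settings,
                     source_label = sprintf("lambda=%g", lambda_value),
                     u_low = ul, u_high = uh)
  } else {
    S <- system$solvent$n_sites
    uarr <- array(numeric(0), dim = c(3, max(S, 1), 0))
    warr <- array(numeric(0), dim = c(3, max(S, 1), 0))
    ul <- uh <- numeric(0)
    for (r in seq_len(settings$n_replicates)) {
      s <- child_seed(settings$seed, "equilibrate", r)
      res <- bath_sample_cpp(es, lambda_value, settings$n_equil_steps,
                             settings$n_prod_steps, settings$save_every,
                             seed = s)
      if (n_save > 0) {
        uarr <- array(c(uarr, res$orientations), dim = c(3, max(S, 1), dim(uarr)[3] + n_save))
        warr <- array(c(warr, res$angvel), dim = c(3, max(S, 1), dim(warr)[3] + n_save))
        ul <- c(ul, res$u_low); uh <- c(uh, res$u_high)
      }
    }
    new_restart_pool("bath", lambda_value,
                     list(orientations = uarr, angvel = warr),
                     reps, steps, steps * settings$timestep, settings,
                     source_label = sprintf("lambda=%g", lambda_value),
                     n_sites = S, sites = system$solvent$site_positions,
                     u_low = ul, u_high = uh)
  }
}

#' Select switch starting points from a restart pool
#'
#' Returns every `stride`-th configuration, preserving order and provenance
#' (the field workflow: restart files saved during equilibrium production,
#' every 40th of 8000 selected, giving 200 switch starts).
#'
#' @param pool A `restart_pool`.
#' @param stride Positive integer stride.
#' @return A `restart_pool` with the selected configurations.
#' @examples
#' \dontrun{
#' starts <- select_switch_starts(pool, 40)  # 8000 -> 200
#' }
#' @export
select_switch_starts <- function(pool, stride) {
  stopifnot(inherits(pool, "restart_pool"))
  check_count(stride, "stride", min = 1L)
  n <- length(pool)
  if (n == 0L) return(pool)
  pool[seq(1L, n, by = stride)]
}

#' Staged equilibrium sampling for BAR
#'
#' Samples the hybrid potential at each coupling value and returns, for every
#' saved frame, its reduced energy \eqn{\beta U(\lambda')} re-evaluated at
#' all coupling values (possible because the hybrid energy is linear in
#' \eqn{\lambda}, so storing the two endpoint energies suffices).
#'
#' @param system A `dual_level_system`.
#' @param lambdas Increasing coupling values; must include at least 2 states.
#' @param settings A [sampler_settings()].
#' @return An object of class `staged_energies`: a list of per-state reduced
#'   energy matrices (rows = samples, columns = states) plus replicate
#'   provenance.
#' @export
sample_staged <- function(system, lambdas, settings) {
  stopifnot(inherits(system, "dual_level_system"),
            inherits(settings, "sampler_settings"))
  if (length(lambdas) < 2L || is.unsorted(lambdas, strictly = TRUE))
    stopf("invalid parameter: `lambdas` must be >= 2 strictly increasing values")
  K <- length(lambdas)
  u_list <- vector("list", K)
  rep_list <- vector("list", K)
  beta <- system$thermo$beta
  for (s in seq_len(K)) {
    st <- settings
    st$seed <- child_seed(settings$seed, "staged", s)
    pool <- sample_equilibrium(system, lambdas[s], st)
    umat <- outer(pool$u_low, 1 - lambdas) + outer(pool$u_high, lambdas)
    u_list[[s]] <- beta * umat
    colnames(u_list[[s]]) <- sprintf("lambda_%g", lambdas)
    rep_list[[s]] <- pool$replicate
  }
  structure(
    list(u = u_list, lambdas = lambdas, beta = beta, replicates = rep_list),
    class = "staged_energies"
  )
}
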