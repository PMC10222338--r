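#' Double free energy difference
#'
#' Deviation of an estimate from the reference value; with a `correction`
#' (the staged low-level charge-change leg of an indirect route) the
#' reported value is `correction + estimate - reference`.
#'
#' @param estimate Estimated \eqn{\Delta A} (kcal/mol).
#' @param reference Reference \eqn{\Delta A} (kcal/mol).
#' @param correction Optional \eqn{\Delta A} of the low-level leg
#'   (kcal/mol).
#' @return \eqn{\delta \Delta A} in kcal/mol.
#' @examples
#' delta_delta_a(0.3, 0.6, correction = 0.5)  # 0.2
#' @export
delta_delta_a <- function(estimate, reference, correction = NULL) {
  if (is.null(correction)) estimate - reference
  else correction + estimate - reference
}

charges_of <- function(x) if (inherits(x, "charge_set")) x$charges else as.numeric(x)

#' Root-mean-square deviation between two charge sets
#'
#' \eqn{RMSD_q = \sqrt{ \frac{1}{N} \sum_i (q_i^{method} - q_i^{ref})^2 }}.
#'
#' @param q_method,q_ref [charge_set()]s (or numeric vectors) of equal
#'   length.
#' @return RMSD in e.
#' @examples
#' rmsd_q(c(0.3, 0), c(0, 0.1))  # sqrt(0.05)
#' @export
rmsd_q <- function(q_method, q_ref) {
  a <- charges_of(q_method); b <- charges_of(q_ref)
  if (length(a) != length(b))
    stopf("input error: charge sets have different lengths (%d vs %d)",
          length(a), length(b))
  sqrt(mean((a - b)^2))
}

#' Differential dipole moment between two charge sets
#'
#' \eqn{\Delta\vec\mu = \sum_i (q_i^{method} - q_i^{ref}) \vec r_i}.  When
#' the two sets have equal net charge the result is origin-independent.
#'
#' @param q_method,q_ref [charge_set()]s or numeric vectors.
#' @param coordinates `n x 3` atom coordinates (Angstrom).
#' @return A list with `vector` (e Angstrom, length 3) and `magnitude_debye`
#'   (1 e Angstrom = 4.80320 D).
#' @export
differential_dipole <- function(q_method, q_ref, coordinates) {
  a <- charges_of(q_method); b <- charges_of(q_ref)
  coordinates <- as.matrix(coordinates)
  if (length(a) != length(b) || length(a) != nrow(coordinates))
    stopf("input error: charges and coordinates must have matching atom counts")
  v <- colSums((a - b) * coordinates)
  list(vector = v, magnitude_debye = sqrt(sum(v^2)) * .ea_to_debye)
}

dipole_vector <- function(q, coordinates) colSums(charges_of(q) * as.matrix(coordinates))

#' Angle between the dipole moments of two charge representations
#'
#' Arc-cosine of the normalized dot product of the two full dipole vectors
#' (not the differential dipole), in degrees.
#'
#' @param q_method,q_ref [charge_set()]s or numeric vectors.
#' @param coordinates `n x 3` atom coordinates (Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
dipole_angle <- function(q_method, q_ref, coordinates) {
  ma <- dipole_vector(q_method, coordinates)
  mb <- dipole_vector(q_ref, coordinates)
  na <- sqrt(sum(ma^2)); nb <- sqrt(sum(mb^2))
  if (na == 0 || nb == 0)
    stopf("undefined-angle error: zero-magnitude dipole moment")
  acos(max(-1, min(1, sum(ma * mb) / (na * nb)))) * 180 / pi
}

#' Count solvent sites in the first solvation shell
#'
#' Number of solvent reference points within `cutoff` (inclusive) of any
#' heavy solute atom.
#'
#' @param solvent_xyz `n x 3` solvent reference coordinates (Angstrom); a
#'   [bath_configuration()]-bearing [restart_pool][sample_equilibrium()]'s
#'   `sites` matrix can be passed directly.
#' @param solute_xyz `m x 3` solute coordinates (Angstrom).
#' @param cutoff Shell cutoff in Angstrom (default 3.0, inclusive).
#' @param heavy Logical vector marking non-hydrogen solute atoms (default
#'   all).
#' @return Integer count.
#' @examples
#' count_first_shell(rbind(c(3, 0, 0)), rbind(c(0, 0, 0)))  # 1 (<= 3 A)
#' @export
count_first_shell <- function(solvent_xyz, solute_xyz, cutoff = 3.0,
                              heavy = NULL) {
  check_number(cutoff, "cutoff", positive = TRUE)
  solvent_xyz <- as.matrix(solvent_xyz)
  solute_xyz <- as.matrix(solute_xyz)
  if (is.null(heavy)) heavy <- rep(TRUE, nrow(solute_xyz))
  su <- solute_xyz[heavy, , drop = FALSE]
  if (nrow(solvent_xyz) == 0L || nrow(su) == 0L) return(0L)
  d2 <- outer(rowSums(solvent_xyz^2), rowSums(su^2), "+") -
    2 * solvent_xyz %*% t(su)
  sum(apply(d2, 1, min) <= cutoff^2 + 1e-12)
}

pool_frames <- function(x) {
  if (inherits(x, "restart_pool")) {
    if (length(x) == 0L) stopf("input error: empty restart pool")
    lapply(seq_len(length(x)), function(i) x$sites)
  } else if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) stopf("input error: empty trajectory")
    lapply(x, as.matrix)
  } else {
    list(as.matrix(x))
  }
}

#' Difference in mean first-shell occupancy between two trajectories
#'
#' Mean shell count over the method trajectory minus the mean over the
#' reference trajectory (the target high level), a static probe of how a
#' charge representation restructures the solvent in contact with the
#' solute.
#'
#' @param traj_method,traj_ref Lists of per-frame solvent coordinate
#'   matrices, or [restart_pool][sample_equilibrium()]s (whose fixed site
#'   positions are used for every frame).
#' @param solute_xyz `m x 3` solute coordinates.
#' @param cutoff Shell cutoff (Angstrom, inclusive).
#' @param heavy Logical vector marking non-hydrogen solute atoms.
#' @return Signed mean count difference.
#' @export
delta_n_waters <- function(traj_method, traj_ref, solute_xyz, cutoff = 3.0,
                           heavy = NULL) {
  fm <- pool_frames(traj_method)
  fr <- pool_frames(traj_ref)
  cm <- vapply(fm, count_first_shell, 0L, solute_xyz = solute_xyz,
               cutoff = cutoff, heavy = heavy)
  cr <- vapply(fr, count_first_shell, 0L, solute_xyz = solute_xyz,
               cutoff = cutoff, heavy = heavy)
  mean(cm) - mean(cr)
}

#' Ensemble-averaged Stokes-shift relaxation
#'
#' Averages per-trajectory energy-gap series \eqn{\Delta U(t)} elementwise,
#' estimates the long-time baseline \eqn{\overline{\Delta U(\infty)}} by
#' time-averaging over `baseline_window`, and returns the shifted series
#' \eqn{\overline{\Delta\Delta U(t)} = \overline{\Delta U(t)} -
#' \overline{\Delta U(\infty)}} -- an unnormalized Stokes shift.
#'
#' @param gap_series Numeric matrix (rows = time points, columns =
#'   trajectories) or a list of equal-length numeric vectors on a common
#'   time grid.
#' @param times Time grid in fs (strictly increasing).
#' @param baseline_window Length-2 vector `(t_start, t_end)` in fs; default
#'   the final 20 percent of the series (for a 10 ps series sampled at 1 fs
#'   this averages the last 2000 entries, 8-10 ps).
#' @return An object of class `stokes_series` with fields `times`,
#'   `mean_gap`, `baseline`, `shifted` and `n_trajectories`.
#' @export
stokes_relaxation <- function(gap_series, times, baseline_window = NULL) {
  if (is.list(gap_series) && !is.data.frame(gap_series))
    gap_series <- do.call(cbind, gap_series)
  gap_series <- as.matrix(gap_series)
  if (length(times) != nrow(gap_series))
    stopf("input error: `times` length does not match the series")
  if (is.unsorted(times, strictly = TRUE))
    stopf("input error: `times` must be strictly increasing")
  if (is.null(baseline_window)) {
    t_end <- times[length(times)]
    baseline_window <- c(times[1] + 0.8 * (t_end - times[1]), t_end)
  }
  in_win <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(in_win))
    stopf("input error: baseline window [%g, %g] fs lies outside the time grid",
          baseline_window[1], baseline_window[2])
  mean_gap <- rowMeans(gap_series)
  baseline <- mean(mean_gap[in_win])
  structure(
    list(times = times, mean_gap = mean_gap, baseline = baseline,
         shifted = mean_gap - baseline,
         n_trajectories = ncol(gap_series),
         baseline_window = baseline_window,
         n_baseline_entries = sum(in_win)),
    class = "stokes_series"
  )
}

#' @export
print.stokes_series <- function(x, ...) {
  cat(sprintf("<stokes_series> %d trajectories, %d time points (%g-%g fs), baseline %.4g kcal/mol over [%g, %g] fs\n",
              x$n_trajectories, length(x$times), x$times[1],
              x$times[length(x$times)], x$baseline,
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Mono-exponential fit of the Stokes-shift decay
#'
#' Nonlinear least squares of \eqn{\Delta U_0 e^{-t/\tau}} to the shifted
#' series restricted to \eqn{t \ge} `discard`.  The initial 0.5 ps are
#' discarded by default so that the fitted time constant corresponds to the
#' slower solvent-reorientation process, not the sub-picosecond one.
#' Initial guesses come from a log-linear regression on the positive
#' segment; no additive offset is fitted (the baseline is already
#' subtracted).
#'
#' @param series A [stokes_relaxation()] result.
#' @param discard Initial time span to discard (fs).
#' @return An object of class `exp_fit` with `amplitude` (\eqn{\Delta U_0},
#'   kcal/mol), `tau` (fs), `discard_window` (fs) and `fit_rss`.
#' @export
fit_mono_exponential <- function(series, discard = 500) {
  stopifnot(inherits(series, "stokes_series"))
  check_number(discard, "discard", nonneg = TRUE)
  keep <- series$times >= discard
  t <- series$times[keep]
  y <- series$shifted[keep]
  if (length(t) < 10L)
    stopf("input error: fewer than 10 points after discarding the first %g fs", discard)
  pos <- y > 0
  if (sum(pos) < 3L || max(y) <= 0)
    stopf("fit-degenerate error: shifted series is not positive over the fit window")
  # log-linear initial guess on the positive segment, with a small grid of
  # fallback time constants in case the tail noise spoils the regression
  lf <- lm(log(y[pos]) ~ t[pos])
  tau0 <- -1 / coef(lf)[2]
  span <- diff(range(t))
  cand <- unique(c(if (is.finite(tau0) && tau0 > 0) tau0,
                   span / 10, span / 3, span))
  rss0 <- vapply(cand, function(tc) {
    a <- sum(y * exp(-t / tc)) / sum(exp(-2 * t / tc))
    sum((y - a * exp(-t / tc))^2)
  }, 0)
  tau0 <- cand[which.min(rss0)]
  a0 <- sum(y * exp(-t / tau0)) / sum(exp(-2 * t / tau0))
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-t / tau),
    start = list(A = a0, tau = tau0),
    lower = c(-Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- coef(fit)
  if (p[["tau"]] <= 0) stopf("fit-degenerate error: non-positive relaxation time")
  structure(
    list(amplitude = unname(p[["A"]]), tau = unname(p[["tau"]]),
         discard_window = discard,
         fit_rss = sum(residuals(fit)^2)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> dU0 = %.4g kcal/mol, tau = %.4g fs (discard %g fs, RSS %.3g)\n",
              x$amplitude, x$tau, x$discard_window, x$fit_rss))
  invisible(x)
}

#' Evaluate a mono-exponential fit
#'
#' \eqn{\Delta U_0 e^{-t/\tau}}; e.g. the residual solvent-relaxation gap at
#' the intended switching length.
#'
#' @param fit An [fit_mono_exponential()] result (or list with `amplitude`
#'   and `tau`).
#' @param t Time(s) in fs.
#' @return Value(s) in kcal/mol.
#' @examples
#' evaluate_fit_at(list(amplitude = 10.5, tau = 1000), 2000)  # 10.5 * exp(-2)
#' @export
evaluate_fit_at <- function(fit, t) {
  fit$amplitude * exp(-t / fit$tau)
}

#' Simulate a Stokes-shift relaxation ensemble
#'
#' Restarts high-level dynamics from equilibrium configurations of a lower
#' state (the system's low level, e.g. MM or a MULL intermediate) and
#' records the energy gap \eqn{\Delta U(t) = U_{high}(t) - U_{low}(t)} per
#' trajectory -- the computational analog of monitoring the solvation
#' response after an instantaneous change of the solute's charge
#' distribution.
#'
#' @param system A dipole-bath `dual_level_system` whose low level carries
#'   the charges of the starting state.
#' @param starts A `restart_pool` equilibrated at the starting state.
#' @param length_fs Trajectory length (fs).
#' @param record_every Record the gap every this many steps.
#' @param timestep Timestep (fs).
#' @param seed Master seed (per-trajectory child seeds).
#' @return A list with `times` (fs) and `gaps` (matrix, rows = time points,
#'   columns = trajectories), ready for [stokes_relaxation()].
#' @export
simulate_stokes_ensemble <- function(system, starts, length_fs = 4000,
                                     record_every = 4, timestep = 1,
                                     seed = 1) {
  stopifnot(inherits(system, "dipole_bath"), inherits(starts, "restart_pool"))
  if (length(starts) == 0L) stopf("input error: empty start pool")
  n_steps <- as.integer(round(length_fs / timestep))
  es <- engine_sys(system, dt = timestep)
  seeds <- vapply(seq_len(length(starts)),
                  function(i) child_seed(seed, "stokes", i), 0)
  gaps <- bath_relax_cpp(es, starts$data$orientations, starts$data$angvel,
                         n_steps, as.integer(record_every), seeds)
  list(times = seq(0, n_steps, by = record_every) * timestep, gaps = gaps)
}

#' Mean absolute deviation and spread of a set of deviations
#'
#' Protocol-level summary of per-system \eqn{\delta\Delta A} values: the
#' mean of the absolute deviations plus the smallest and largest absolute
#' deviation.
#'
#' @param values Numeric \eqn{\delta\Delta A} values (kcal/mol), non-empty.
#' @return An object of class `protocol_summary` with
#'   `per_item_delta_delta_a`, `mad`, `spread_min` and `spread_max`.
#' @examples
#' mad_and_spread(c(0.1, -0.2, 0.3))  # MAD 0.2, spread 0.1 - 0.3
#' @export
mad_and_spread <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("input error: empty value list")
  a <- abs(values)
  structure(
    list(per_item_delta_delta_a = values, mad = mean(a),
         spread_min = min(a), spread_max = max(a)),
    class = "protocol_summary"
  )
}

#' @export
print.protocol_summary <- function(x, ...) {
  cat(sprintf("<protocol_summary> n = %d, MAD = %.4g kcal/mol, spread [%.4g, %.4g]\n",
              length(x$per_item_delta_delta_a), x$mad, x$spread_min, x$spread_max))
  invisible(x)
}
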