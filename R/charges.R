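#' Charge set
#'
#' Per-atom partial charges with provenance.  All charge sets are
#' re-neutralized to the declared net charge by uniform subtraction of the
#' excess per atom, so that dipole comparisons are not corrupted by net
#' charge drift.
#'
#' @param charges Per-atom charges (e).
#' @param atom_labels Optional labels.
#' @param source Provenance label: `"MM"`, `"MULL(gas)"`, `"MULL(solv)"`,
#'   `"MULL(solv*)"`, `"interpolated"`, `"instantaneous"` or custom.
#' @param n_configs_averaged Number of configurations averaged (1 for fixed
#'   sets).
#' @param per_atom_std Optional per-atom standard deviations (e, n-1
#'   denominator) of the averaged charges.
#' @param net_charge Declared net charge (e).
#' @param neutralize If `TRUE` (default) re-neutralize; otherwise the sum
#'   must already match `net_charge` within 1e-10 e.
#' @return An object of class `charge_set`.
#' @export
charge_set <- function(charges, atom_labels = NULL, source = "MM",
                       n_configs_averaged = 1L, per_atom_std = NULL,
                       net_charge = 0, neutralize = TRUE) {
  charges <- as.numeric(charges)
  n <- length(charges)
  if (n < 1L) stopf("input error: empty charge set")
  if (neutralize) {
    charges <- charges - (sum(charges) - net_charge) / n
  } else if (abs(sum(charges) - net_charge) > 1e-10) {
    stopf("input error: charges sum to %.12g, declared net charge is %g",
          sum(charges), net_charge)
  }
  if (is.null(atom_labels)) atom_labels <- paste0("A", seq_len(n))
  if (!is.null(per_atom_std) && length(per_atom_std) != n)
    stopf("input error: `per_atom_std` length mismatch")
  structure(
    list(charges = charges, atom_labels = as.character(atom_labels),
         source = source, n_configs_averaged = as.integer(n_configs_averaged),
         per_atom_std = per_atom_std, net_charge = net_charge),
    class = "charge_set"
  )
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set %s> %d atoms, net charge %g e (averaged over %d configs)\n",
              x$source, length(x$charges), x$net_charge, x$n_configs_averaged))
  df <- data.frame(atom = x$atom_labels, charge_e = x$charges)
  if (!is.null(x$per_atom_std)) df$std_e <- x$per_atom_std
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
length.charge_set <- function(x) length(x$charges)

#' Derive an averaged hybrid ("MULL") charge set from a restart pool
#'
#' Evaluates the configuration-dependent high-level charges on `n_samples`
#' evenly spaced configurations of the pool (deterministic stride selection
#' across replicates), averages per atom, records the per-atom standard
#' deviation (n-1 denominator), and re-neutralizes the mean set.  The source
#' label is inferred from the pool's provenance: a gas-phase low-level pool
#' gives `MULL(gas)`, a solvated low-level pool `MULL(solv)` and a solvated
#' high-level pool `MULL(solv*)`.
#'
#' @param system The dipole-bath `dual_level_system` the pool belongs to.
#' @param pool A `restart_pool` sampled from `system` (at either level).
#' @param n_samples Number of configurations to average (default 200:
#'   25 per replicate for the standard 8-replicate pool).
#' @return A [charge_set()] with per-atom standard deviations.
#' @export
derive_average_charges <- function(system, pool, n_samples = 200) {
  stopifnot(inherits(system, "dipole_bath"), inherits(pool, "restart_pool"))
  n <- length(pool)
  if (n == 0L) stopf("input error: empty restart pool")
  check_count(n_samples, "n_samples", min = 1L)
  if (n_samples > n)
    stopf("input error: n_samples (%d) exceeds pool size (%d)", n_samples, n)
  idx <- ceiling(seq_len(n_samples) * n / n_samples)
  qmat <- vapply(idx, function(i) {
    high_level_charges(system, pool$data$orientations[, , i])$charges
  }, numeric(system$solute$n_atoms))
  qmat <- matrix(qmat, nrow = system$solute$n_atoms)
  qmean <- rowMeans(qmat)
  qstd <- if (n_samples > 1) apply(qmat, 1, sd) else rep(0, nrow(qmat))
  src <- if (system$solvent$n_sites == 0) "MULL(gas)"
         else if (isTRUE(all.equal(pool$lambda, 1))) "MULL(solv*)"
         else if (isTRUE(all.equal(pool$lambda, 0))) "MULL(solv)"
         else sprintf("MULL(lambda=%g)", pool$lambda)
  charge_set(qmean, atom_labels = system$solute$atom_labels, source = src,
             n_configs_averaged = n_samples, per_atom_std = qstd,
             net_charge = system$solute$net_charge)
}

#' Interpolate between two charge sets
#'
#' Per-atom convex combination \eqn{q_i(\lambda) = (1-\lambda) q_i^{low} +
#' \lambda q_i^{target}}; endpoints are returned exactly.
#'
#' @param q_low,q_target [charge_set()]s with matching atom counts.
#' @param lambda_value Mixing fraction in `[0, 1]`.
#' @return A `charge_set` with source `"interpolated"` (or the endpoint's
#'   source at \eqn{\lambda \in \{0, 1\}}).
#' @export
interpolate_charges <- function(q_low, q_target, lambda_value) {
  stopifnot(inherits(q_low, "charge_set"), inherits(q_target, "charge_set"))
  check_fraction(lambda_value, "lambda_value")
  if (length(q_low) != length(q_target))
    stopf("input error: charge sets have different atom counts (%d vs %d)",
          length(q_low), length(q_target))
  if (lambda_value == 0) return(q_low)
  if (lambda_value == 1) return(q_target)
  q <- (1 - lambda_value) * q_low$charges + lambda_value * q_target$charges
  net <- (1 - lambda_value) * q_low$net_charge + lambda_value * q_target$net_charge
  charge_set(q, atom_labels = q_low$atom_labels, source = "interpolated",
             net_charge = net, neutralize = FALSE)
}

#' Build the charge ladder for the staged low-level leg
#'
#' Maps [interpolate_charges()] over a set of coupling values; the default
#' ladder uses three equidistant intermediates between the end states.
#'
#' @param q_low,q_target End-state [charge_set()]s.
#' @param lambdas Coupling values (default `c(0, 0.25, 0.5, 0.75, 1)`).
#' @return A list of `charge_set`s.
#' @export
charge_ladder <- function(q_low, q_target, lambdas = c(0, 0.25, 0.5, 0.75, 1)) {
  lapply(lambdas, function(l) interpolate_charges(q_low, q_target, l))
}

#' Hybrid charge intermediate system
#'
#' Returns a system whose low level uses the supplied fixed charges (all
#' other low-level terms unchanged) -- the MULL intermediate state -- while
#' the high level remains the original responsive-charge level, enabling
#' MULL-to-high switching.
#'
#' @param system A dipole-bath `dual_level_system`.
#' @param charge_set A [charge_set()] with the solute's atom count.
#' @return A `dual_level_system` of kind `"dipole_bath"`.
#' @export
make_intermediate_system <- function(system, charge_set) {
  stopifnot(inherits(system, "dipole_bath"), inherits(charge_set, "charge_set"))
  if (length(charge_set) != system$solute$n_atoms)
    stopf("input error: charge set has %d atoms, solute has %d",
          length(charge_set), system$solute$n_atoms)
  out <- system
  out$q_low <- charge_set$charges
  out$kappa_low <- rep(0, system$solute$n_atoms)
  out$label_low <- charge_set$source
  out
}

#' Fixed-charge perturbation system for the staged leg
#'
#' A dual-level system whose two levels are both fixed-charge states of the
#' same solute (e.g. the force-field charges and a MULL average).  Because
#' the electrostatic energy is linear in the charges, the hybrid energy at
#' coupling \eqn{\lambda} equals the energy of the interpolated charge set
#' \eqn{q_i(\lambda)}, so staged sampling of this system is exactly the
#' charge-interpolation ladder.
#'
#' @param system A dipole-bath `dual_level_system` (supplies geometry,
#'   solvent and thermodynamic state).
#' @param q_from,q_to End-state [charge_set()]s.
#' @return A `dual_level_system` of kind `"dipole_bath"` with fixed charges
#'   on both levels.
#' @export
charge_perturbation_system <- function(system, q_from, q_to) {
  stopifnot(inherits(system, "dipole_bath"))
  out <- system
  out$q_low <- q_from$charges
  out$kappa_low <- rep(0, system$solute$n_atoms)
  out$offset_low <- 0
  out$q_high <- q_to$charges
  out$kappa_high <- rep(0, system$solute$n_atoms)
  out$offset_high <- 0
  out$label_low <- q_from$source
  out$label_high <- q_to$source
  out
}

#' Free energy of the low-level charge-change leg by staged BAR
#'
#' Computes \eqn{\Delta A(MM \leftrightarrow MULL)} for the transformation
#' from the system's current low-level charges to `q_target`, using
#' equilibrium sampling at the interpolated-charge states and pairwise
#' Bennett estimation ([staged_bar()]).
#'
#' @param system A dipole-bath `dual_level_system`.
#' @param q_target Target [charge_set()].
#' @param settings A [sampler_settings()].
#' @param lambdas Ladder coupling values (default three equidistant
#'   intermediates).
#' @return A `free_energy_estimate`.
#' @export
delta_a_charge_leg <- function(system, q_target, settings,
                               lambdas = c(0, 0.25, 0.5, 0.75, 1)) {
  q_from <- charge_set(system$q_low,
                       atom_labels = system$solute$atom_labels,
                       source = system$label_low,
                       net_charge = sum(system$q_low),
                       neutralize = FALSE)
  pert <- charge_perturbation_system(system, q_from, q_target)
  staged_bar(sample_staged(pert, lambdas, settings))
}
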