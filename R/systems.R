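#' Solute specification
#'
#' A rigid solute: fixed coordinates, per-atom baseline partial charges and
#' per-atom response coefficients coupling each atom's high-level charge to
#' the local electrostatic potential from the solvent (the linear
#' charge-response stand-in for a semi-empirical solute whose converged
#' charges change with the environment).
#'
#' @param coordinates Numeric `n x 3` matrix of atom positions (Angstrom).
#' @param base_charges Numeric vector of per-atom charges (e); must sum to
#'   `net_charge` within 1e-10.
#' @param response_coefficients Per-atom coupling of the high-level charge to
#'   the local electrostatic potential, in e per (kcal/mol/e).  Scalar values
#'   are recycled.  Zero gives a fixed-charge (purely "MM") high level.
#' @param net_charge Declared net charge (e); 0 for all shipped fixtures.
#' @param atom_labels Optional character labels, defaults to `A1`, `A2`, ...
#' @param heavy Logical vector marking non-hydrogen atoms (used by the
#'   first-solvation-shell analysis); defaults to all `TRUE`.
#' @return An object of class `solute_spec`.
#' @export
solute_spec <- function(coordinates, base_charges, response_coefficients = 0,
                        net_charge = 0, atom_labels = NULL, heavy = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L)
    stopf("invalid parameter: `coordinates` must be an n x 3 matrix")
  n <- nrow(coordinates)
  if (n < 1L) stopf("invalid parameter: solute needs at least one atom")
  if (!all(is.finite(coordinates)))
    stopf("invalid parameter: solute coordinates must be finite")
  if (length(base_charges) != n)
    stopf("invalid parameter: `base_charges` length must match atom count")
  if (abs(sum(base_charges) - net_charge) > 1e-10)
    stopf("invalid parameter: base charges sum to %.12g, declared net charge is %g",
          sum(base_charges), net_charge)
  if (length(response_coefficients) == 1L)
    response_coefficients <- rep(response_coefficients, n)
  if (length(response_coefficients) != n)
    stopf("invalid parameter: `response_coefficients` length must match atom count")
  if (is.null(atom_labels)) atom_labels <- paste0("A", seq_len(n))
  if (is.null(heavy)) heavy <- rep(TRUE, n)
  structure(
    list(n_atoms = n, coordinates = unname(coordinates),
         base_charges = as.numeric(base_charges),
         response_coefficients = as.numeric(response_coefficients),
         net_charge = net_charge, atom_labels = as.character(atom_labels),
         heavy = as.logical(heavy)),
    class = "solute_spec"
  )
}

#' Solvent specification: a bath of dipolar rotors
#'
#' Point-dipole rotors at fixed positions; only their orientations move,
#' under rotational Langevin dynamics.  This is the minimal solvent model
#' that exhibits dielectric reorientation with a finite relaxation time.
#'
#' @param site_positions Numeric `n x 3` matrix of rotor positions (Angstrom);
#'   `NULL` or a 0-row matrix gives a gas-phase (solvent-free) system.
#' @param dipole_magnitude Rotor dipole moment (e Angstrom).
#' @param rotational_friction Langevin friction on the rotor orientation
#'   (1/ps).
#' @param inertia Rotor moment of inertia (amu Angstrom^2).
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(site_positions = NULL, dipole_magnitude = 0.49,
                         rotational_friction = 2000, inertia = 200) {
  if (is.null(site_positions))
    site_positions <- matrix(numeric(0), ncol = 3)
  site_positions <- as.matrix(site_positions)
  if (ncol(site_positions) != 3L && nrow(site_positions) > 0L)
    stopf("invalid parameter: `site_positions` must be an n x 3 matrix")
  check_number(dipole_magnitude, "dipole_magnitude", nonneg = TRUE)
  check_number(rotational_friction, "rotational_friction", positive = TRUE)
  check_number(inertia, "inertia", positive = TRUE)
  structure(
    list(n_sites = nrow(site_positions),
         site_positions = unname(site_positions),
         dipole_magnitude = dipole_magnitude,
         rotational_friction = rotational_friction, inertia = inertia),
    class = "solvent_spec"
  )
}

#' Harmonic dual-level pair (closed-form oracle system)
#'
#' A single 1-D particle with \eqn{U_{low} = k_{low} x^2 / 2} and
#' \eqn{U_{high} = k_{high} (x - x_0)^2 / 2}.  The free energy difference has
#' the closed form \eqn{\Delta A = (k_B T / 2) \ln(k_{high}/k_{low})} (the
#' offset shifts the well but not the partition function), which makes this
#' system the package's exact oracle for every estimator.
#'
#' @param k_low,k_high Force constants (kcal/mol/Angstrom^2), > 0.
#' @param offset Displacement of the high-level minimum (Angstrom).
#' @param thermo A [thermo_state()].
#' @param mass Particle mass (amu).
#' @param friction Langevin friction (1/ps).
#' @param label_low,label_high Identifiers for the two levels.
#' @return A `dual_level_system` of kind `"harmonic"` with field
#'   `analytic_delta_a` (kcal/mol).
#' @examples
#' sys <- make_harmonic_pair(1, 4, thermo = thermo_state_kT(0.6))
#' sys$analytic_delta_a  # 0.3 * log(4)
#' @export
make_harmonic_pair <- function(k_low, k_high, offset = 0,
                               thermo = thermo_state(), mass = 12,
                               friction = 5, label_low = "low",
                               label_high = "high") {
  check_number(k_low, "k_low", positive = TRUE)
  check_number(k_high, "k_high", positive = TRUE)
  check_number(offset, "offset")
  check_number(mass, "mass", positive = TRUE)
  check_number(friction, "friction", positive = TRUE)
  stopifnot(inherits(thermo, "thermo_state"))
  structure(
    list(kind = "harmonic", k_low = k_low, k_high = k_high,
         x0_low = 0, x0_high = offset, mass = mass, friction = friction,
         thermo = thermo,
         analytic_delta_a = 0.5 * (1 / thermo$beta) * log(k_high / k_low),
         label_low = label_low, label_high = label_high),
    class = c("harmonic_pair", "dual_level_system")
  )
}

#' Dipole-bath dual-level system
#'
#' Low level: the solute's fixed `base_charges` interacting with the rotor
#' dipoles through Coulomb charge-dipole terms.  High level: the same
#' functional form, but with each atom's charge replaced by the
#' environment-responsive value
#' \eqn{q_i = q_i^0 + \kappa_i \phi_i} (re-neutralized to the declared net
#' charge), where \eqn{\phi_i} is the electrostatic potential at atom i from
#' the rotors.  An optional constant `level_offset` models an intrinsic
#' (gas-phase) energy difference between the levels.  There is no closed-form
#' \eqn{\Delta A}; [brute_force_delta_a()] is the oracle.
#'
#' @param solute A [solute_spec()].
#' @param solvent A [solvent_spec()].
#' @param thermo A [thermo_state()].
#' @param level_offset Constant added to the high-level energy (kcal/mol).
#' @param label_low,label_high Identifiers for the two levels.
#' @return A `dual_level_system` of kind `"dipole_bath"`.
#' @export
make_dipole_bath_system <- function(solute, solvent, thermo = thermo_state(),
                                    level_offset = 0, label_low = "MM",
                                    label_high = "high") {
  stopifnot(inherits(solute, "solute_spec"), inherits(solvent, "solvent_spec"),
            inherits(thermo, "thermo_state"))
  check_number(level_offset, "level_offset")
  if (solvent$n_sites > 0) {
    d2 <- outer(rowSums(solute$coordinates^2),
                rowSums(solvent$site_positions^2), "+") -
      2 * solute$coordinates %*% t(solvent$site_positions)
    if (min(d2) < 0.5^2)
      stopf("geometry error: solute atom and solvent site closer than 0.5 Angstrom (min distance %.3g)",
            sqrt(max(min(d2), 0)))
  }
  structure(
    list(kind = "dipole_bath", solute = solute, solvent = solvent,
         thermo = thermo,
         q_low = solute$base_charges,
         kappa_low = rep(0, solute$n_atoms),
         offset_low = 0,
         q_high = solute$base_charges,
         kappa_high = solute$response_coefficients,
         offset_high = level_offset,
         analytic_delta_a = NULL,
         label_low = label_low, label_high = label_high),
    class = c("dipole_bath", "dual_level_system")
  )
}

#' @export
print.dual_level_system <- function(x, ...) {
  if (x$kind == "harmonic") {
    cat(sprintf("<dual_level_system: harmonic pair> k = %g -> %g kcal/mol/A^2, offset %g A, T = %g K\n",
                x$k_low, x$k_high, x$x0_high - x$x0_low, x$thermo$temperature))
    cat(sprintf("  analytic delta A = %.6g kcal/mol\n", x$analytic_delta_a))
  } else {
    cat(sprintf("<dual_level_system: dipole bath> %d solute atoms, %d rotors, T = %g K\n",
                x$solute$n_atoms, x$solvent$n_sites, x$thermo$temperature))
    cat(sprintf("  levels: %s -> %s\n", x$label_low, x$label_high))
  }
  invisible(x)
}

# engine-facing parameter list (internal)
engine_sys <- function(system, dt = 1, friction = NULL) {
  if (system$kind == "harmonic") {
    gamma <- if (is.null(friction)) system$friction else friction
    list(k_low = system$k_low, k_high = system$k_high,
         x0_low = system$x0_low, x0_high = system$x0_high,
         mass = system$mass, beta = system$thermo$beta,
         gamma_fs = gamma / 1000, dt = dt)
  } else {
    gamma <- if (is.null(friction)) system$solvent$rotational_friction else friction
    list(coords = t(system$solute$coordinates),
         sites = if (system$solvent$n_sites > 0) t(system$solvent$site_positions)
                 else matrix(numeric(0), nrow = 3),
         q_low = system$q_low, kappa_low = system$kappa_low,
         offset_low = system$offset_low,
         q_high = system$q_high, kappa_high = system$kappa_high,
         offset_high = system$offset_high,
         mu = system$solvent$dipole_magnitude,
         inertia = system$solvent$inertia,
         gamma_fs = gamma / 1000, beta = system$thermo$beta, dt = dt)
  }
}

#' Swap the two levels of a dual-level system
#'
#' Returns the system with the roles of the low and high level exchanged
#' (used for backward switching ensembles; \eqn{\Delta A} changes sign).
#'
#' @param system A `dual_level_system`.
#' @return The reversed `dual_level_system`.
#' @export
reverse_system <- function(system) {
  stopifnot(inherits(system, "dual_level_system"))
  if (system$kind == "harmonic") {
    out <- system
    out$k_low <- system$k_high; out$k_high <- system$k_low
    out$x0_low <- system$x0_high; out$x0_high <- system$x0_low
  } else {
    out <- system
    out$q_low <- system$q_high; out$kappa_low <- system$kappa_high
    out$offset_low <- system$offset_high
    out$q_high <- system$q_low; out$kappa_high <- system$kappa_low
    out$offset_high <- system$offset_low
  }
  out$label_low <- system$label_high
  out$label_high <- system$label_low
  if (!is.null(system$analytic_delta_a))
    out$analytic_delta_a <- -system$analytic_delta_a
  out
}

#' Configuration of a dipole-bath system
#'
#' @param orientations `3 x n_sites` matrix of unit rotor orientations.
#' @param angvel Optional `3 x n_sites` matrix of angular velocities
#'   (rad/fs, perpendicular to the orientations); zero if omitted.
#' @param time_fs Time stamp (fs).
#' @param replicate,step Provenance of the configuration.
#' @return An object of class `bath_configuration`.
#' @export
bath_configuration <- function(orientations, angvel = NULL, time_fs = 0,
                               replicate = NA_integer_, step = NA_integer_) {
  orientations <- as.matrix(orientations)
  if (nrow(orientations) != 3L)
    stopf("invalid parameter: `orientations` must be a 3 x n matrix")
  norms <- sqrt(colSums(orientations^2))
  if (length(norms) && any(abs(norms - 1) > 1e-9))
    stopf("invalid configuration: rotor orientations must have unit norm (max deviation %.3g)",
          max(abs(norms - 1)))
  if (is.null(angvel)) angvel <- matrix(0, 3, ncol(orientations))
  structure(
    list(orientations = unname(orientations), angvel = unname(as.matrix(angvel)),
         time_fs = time_fs, replicate = replicate, step = step),
    class = "bath_configuration"
  )
}

#' Hybrid energy of a configuration
#'
#' The convex combination \eqn{U(\lambda) = (1-\lambda) U_{low} + \lambda
#' U_{high}} used both for equilibrium sampling at intermediate coupling and
#' for work accumulation during switches.
#'
#' @param system A `dual_level_system`.
#' @param config For a harmonic pair, a numeric position (Angstrom); for a
#'   dipole bath, a [bath_configuration()] or a `3 x n_sites` orientation
#'   matrix.
#' @param lambda_value Coupling parameter in `[0, 1]`.
#' @return Energy in kcal/mol.
#' @export
hybrid_energy <- function(system, config, lambda_value) {
  stopifnot(inherits(system, "dual_level_system"))
  check_fraction(lambda_value, "lambda_value")
  if (system$kind == "harmonic") {
    x <- if (is.list(config)) config$x else config
    check_number(x, "config")
    e <- (1 - lambda_value) * 0.5 * system$k_low * (x - system$x0_low)^2 +
      lambda_value * 0.5 * system$k_high * (x - system$x0_high)^2
  } else {
    u <- if (inherits(config, "bath_configuration")) config$orientations else as.matrix(config)
    e <- bath_energy_cpp(engine_sys(system), u, lambda_value)
  }
  if (!is.finite(e)) stopf("numeric error: non-finite energy component")
  e
}

#' Configuration-dependent high-level charges
#'
#' Evaluates the environment-responsive (Mulliken-like) charges of the high
#' level for one configuration: \eqn{q_i = q_i^0 + \kappa_i \phi_i}, with the
#' total re-neutralized to the declared net charge by uniform subtraction of
#' the excess.
#'
#' @param system A dipole-bath `dual_level_system`.
#' @param config A [bath_configuration()] or `3 x n_sites` orientation matrix.
#' @return A [charge_set()] with source `"instantaneous"`.
#' @export
high_level_charges <- function(system, config) {
  stopifnot(inherits(system, "dipole_bath"))
  u <- if (inherits(config, "bath_configuration")) config$orientations else as.matrix(config)
  if (system$solvent$n_sites == 0) {
    phi <- rep(0, system$solute$n_atoms)
  } else {
    phi <- bath_phi_cpp(engine_sys(system), u)
  }
  if (!all(is.finite(phi)))
    stopf("numeric error: non-finite electrostatic potential")
  q <- system$q_high + system$kappa_high * phi
  q <- q - (sum(q) - system$solute$net_charge) / length(q)
  charge_set(q, atom_labels = system$solute$atom_labels,
             source = "instantaneous", n_configs_averaged = 1L,
             net_charge = system$solute$net_charge)
}

# per-level energies for one configuration (internal, used by tests/oracles)
level_energies <- function(system, config) {
  if (system$kind == "harmonic") {
    x <- if (is.list(config)) config$x else config
    c(low = 0.5 * system$k_low * (x - system$x0_low)^2,
      high = 0.5 * system$k_high * (x - system$x0_high)^2)
  } else {
    u <- if (inherits(config, "bath_configuration")) config$orientations else as.matrix(config)
    es <- engine_sys(system)
    c(low = bath_energy_cpp(es, u, 0), high = bath_energy_cpp(es, u, 1))
  }
}

# quasi-uniform points on a sphere of radius r (golden-spiral construction)
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  radius * cbind(r * cos(th), r * sin(th), z)
}

#' Shipped dipole-bath fixture: a polar solute among 64 rotors
#'
#' A rigid four-atom solute with a permanent dipole and negative response
#' coefficients (the solute's charges polarize in the reaction field of the
#' solvent, enhancing its dipole in solution, as a semi-empirical description
#' does), surrounded by 64 dipolar rotors on two spherical shells.  The
#' parameters are fixed so that the high-level charges fluctuate by well
#' under 0.03 e about their means while the mean charges differ appreciably
#' from the base charges -- the statistical structure that makes averaged
#' hybrid charge intermediates meaningful.
#'
#' @param thermo A [thermo_state()]; default 300 K.
#' @return A `dual_level_system` of kind `"dipole_bath"`.
#' @export
polar_solute_system <- function(thermo = thermo_state(300)) {
  solute <- solute_spec(
    coordinates = rbind(c(1.2, 0, 0), c(-1.2, 0, 0),
                        c(0, 1.0, 0.6), c(0, -1.0, 0.6)),
    base_charges = c(0.35, -0.35, 0.20, -0.20),
    response_coefficients = -0.0015
  )
  solvent <- solvent_spec(
    site_positions = rbind(fibonacci_sphere(32, 4.0),
                           fibonacci_sphere(32, 6.5)),
    dipole_magnitude = 0.49,
    rotational_friction = 2000,  # 1/ps
    inertia = 600
  )
  make_dipole_bath_system(solute, solvent, thermo = thermo,
                          label_low = "MM", label_high = "SQM-like")
}

#' Gas-phase variant of a dipole-bath system
#'
#' The same solute with the solvent removed (zero rotor sites); the
#' electrostatic potential at every atom is identically zero, so the
#' high-level charges reduce to the base charges.
#'
#' @param system A dipole-bath `dual_level_system`.
#' @return A `dual_level_system` of kind `"dipole_bath"` without solvent.
#' @export
gas_phase_system <- function(system) {
  stopifnot(inherits(system, "dipole_bath"))
  out <- system
  out$solvent <- solvent_spec(NULL,
                              dipole_magnitude = system$solvent$dipole_magnitude,
                              rotational_friction = system$solvent$rotational_friction,
                              inertia = system$solvent$inertia)
  out
}

#' Brute-force free energy oracle via densely staged BAR
#'
#' Equilibrium sampling at `n_windows` equally spaced coupling values with
#' pairwise Bennett estimation between neighbors; replicate runs provide the
#' standard error.  Serves as the reference \eqn{\Delta A} for systems
#' without a closed form.
#'
#' @param system A `dual_level_system`.
#' @param n_windows Number of coupling windows (>= 5), equally spaced in
#'   `[0, 1]`.
#' @param steps_per_window Production steps per window and replicate.
#' @param seed Master seed.
#' @param n_replicates Independent repetitions (stderr = sd/sqrt(n)).
#' @param settings Optional [sampler_settings()] overriding the defaults.
#' @return A `free_energy_estimate` (method `"BAR-staged"`).
#' @export
brute_force_delta_a <- function(system, n_windows = 11,
                                steps_per_window = 20000, seed = 1,
                                n_replicates = 8, settings = NULL) {
  check_count(n_windows, "n_windows", min = 5L)
  if (is.null(settings)) {
    settings <- sampler_settings(
      n_equil_steps = max(2000, steps_per_window %/% 4),
      n_prod_steps = steps_per_window,
      save_every = max(1L, steps_per_window %/% 50L),
      n_replicates = n_replicates, seed = seed
    )
  }
  lambdas <- seq(0, 1, length.out = n_windows)
  staged <- sample_staged(system, lambdas, settings)
  est <- staged_bar(staged)
  ov <- vapply(est$diagnostics$stages, function(s) s$histogram_overlap, 0)
  if (any(ov < 0.03))
    warning(sprintf(paste("low overlap between neighboring windows (min %.3f);",
                          "consider more windows (narrower spacing)"),
                    min(ov)), call. = FALSE)
  est
}
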