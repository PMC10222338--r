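# Shared fixtures, built lazily and cached for the whole test run.  All
# stochastic fixtures use fixed seeds so the suite is deterministic.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# harmonic oracle pair at kB*T = 0.6 (analytic dA = 0.3 * log 4)
fx_harm <- function() fx("harm", function()
  make_harmonic_pair(1, 4, offset = 0.5, thermo = thermo_state_kT(0.6)))

fx_harm_pool <- function() fx("harm_pool", function()
  sample_equilibrium(fx_harm(), 0, sampler_settings(
    n_equil_steps = 2000, n_prod_steps = 100000, save_every = 50,
    n_replicates = 4, seed = 101)))

fx_harm_pool_hi <- function() fx("harm_pool_hi", function()
  sample_equilibrium(fx_harm(), 1, sampler_settings(
    n_equil_steps = 2000, n_prod_steps = 100000, save_every = 50,
    n_replicates = 4, seed = 102)))

# dipole-bath fixture and its equilibrium pools (8 replicates each)
fx_bath <- function() fx("bath", polar_solute_system)

fx_bath_settings <- function() sampler_settings(
  n_equil_steps = 8000, n_prod_steps = 37500, save_every = 300,
  n_replicates = 8, seed = 201)

fx_pool_mm <- function() fx("pool_mm", function()
  sample_equilibrium(fx_bath(), 0, fx_bath_settings()))

fx_pool_hi <- function() fx("pool_hi", function() {
  st <- fx_bath_settings(); st$seed <- 202
  sample_equilibrium(fx_bath(), 1, st)
})

fx_q_solv <- function() fx("q_solv", function()
  derive_average_charges(fx_bath(), fx_pool_mm(), 200))

fx_q_solv_star <- function() fx("q_solv_star", function()
  derive_average_charges(fx_bath(), fx_pool_hi(), 200))

fx_sys_mull <- function() fx("sys_mull", function()
  make_intermediate_system(fx_bath(), fx_q_solv()))

fx_pool_mull <- function() fx("pool_mull", function() {
  st <- fx_bath_settings(); st$seed <- 203
  sample_equilibrium(fx_sys_mull(), 0, st)
})

# shared expensive estimates used by the ordering and acceptance checks
fx_cro_ref <- function() fx("cro_ref", function() {
  sys <- fx_bath()
  wf <- run_switch_ensemble(sys, select_switch_starts(fx_pool_mm(), 10),
                            switch_settings(5000, seed = 301))
  wb <- run_switch_ensemble(sys, select_switch_starts(fx_pool_hi(), 10),
                            switch_settings(5000, direction = "backward",
                                            seed = 302))
  two_sided(as_work_sample(wf), as_work_sample(wb), n_boot = 0)
})

fx_leg_settings <- function(seed) sampler_settings(
  n_equil_steps = 8000, n_prod_steps = 22500, save_every = 300,
  n_replicates = 8, seed = seed)

fx_leg_solv <- function() fx("leg_solv", function()
  delta_a_charge_leg(fx_bath(), fx_q_solv(), fx_leg_settings(311)))

fx_leg_solv_star <- function() fx("leg_solv_star", function()
  delta_a_charge_leg(fx_bath(), fx_q_solv_star(), fx_leg_settings(312)))

fx_sys_mull_star <- function() fx("sys_mull_star", function()
  make_intermediate_system(fx_bath(), fx_q_solv_star()))

fx_pool_mull_star <- function() fx("pool_mull_star", function() {
  st <- fx_bath_settings(); st$seed <- 204
  sample_equilibrium(fx_sys_mull_star(), 0, st)
})

# tiny 2-atom/1-rotor system for hand-evaluated electrostatics
fx_tiny <- function() fx("tiny", function() {
  solute <- solute_spec(rbind(c(0, 0, 0), c(1.5, 0, 0)), c(0.3, -0.3),
                        response_coefficients = -0.002)
  solvent <- solvent_spec(rbind(c(0, 3, 0)), dipole_magnitude = 0.5,
                          rotational_friction = 2000, inertia = 600)
  make_dipole_bath_system(solute, solvent, thermo_state(300))
})

expect_within_stderr <- function(estimate, truth, n_se = 3) {
  expect_lt(abs(estimate$delta_a - truth), n_se * estimate$stderr)
}
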