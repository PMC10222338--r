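test_that("thermo_state fixes beta = 1/(kB T) to machine precision", {
  th <- thermo_state(300)
  expect_equal(th$beta * th$kB * th$temperature, 1, tolerance = 1e-14)
  expect_equal(1 / thermo_state_kT(0.6)$beta, 0.6, tolerance = 1e-14)
  expect_error(thermo_state(-1), "temperature")
})

test_that("harmonic pair has the closed-form free energy difference", {
  th <- thermo_state_kT(0.6)
  expect_equal(make_harmonic_pair(1, 1, 0, th)$analytic_delta_a, 0)
  expect_equal(make_harmonic_pair(1, 4, 0, th)$analytic_delta_a, 0.3 * log(4))
  # the offset does not change delta A; reversing the pair negates it
  expect_equal(make_harmonic_pair(1, 4, 2.5, th)$analytic_delta_a, 0.3 * log(4))
  expect_equal(make_harmonic_pair(4, 1, 0, th)$analytic_delta_a,
               -make_harmonic_pair(1, 4, 0, th)$analytic_delta_a)
  expect_error(make_harmonic_pair(-1, 4, 0, th), "k_low")
  expect_error(make_harmonic_pair(1, 0, 0, th), "k_high")
})

test_that("reverse_system swaps the levels consistently", {
  sys <- fx_harm()
  rev <- reverse_system(sys)
  expect_equal(rev$analytic_delta_a, -sys$analytic_delta_a)
  x <- 0.7
  expect_equal(hybrid_energy(rev, x, 0), hybrid_energy(sys, x, 1))
  expect_equal(hybrid_energy(rev, x, 1), hybrid_energy(sys, x, 0))

  bath <- fx_bath()
  revb <- reverse_system(bath)
  cfg <- pool_config(fx_pool_mm(), 1)
  expect_equal(hybrid_energy(revb, cfg, 0), hybrid_energy(bath, cfg, 1))
  expect_equal(hybrid_energy(revb, cfg, 0.25), hybrid_energy(bath, cfg, 0.75))
})

test_that("solute/solvent specs enforce their invariants", {
  expect_error(solute_spec(rbind(c(0, 0, 0)), c(0.1), net_charge = 0),
               "net charge")
  expect_error(solute_spec(matrix(Inf, 1, 3), 0), "finite")
  expect_error(solvent_spec(rbind(c(0, 0, 0)), dipole_magnitude = -1),
               "dipole_magnitude")
  # overlapping solute and solvent sites are a geometry error
  sol <- solute_spec(rbind(c(0, 0, 0)), 0)
  sv <- solvent_spec(rbind(c(0.3, 0, 0)))
  expect_error(make_dipole_bath_system(sol, sv), "geometry error")
})

test_that("high-level charges respond to the solvent field and re-neutralize", {
  bath <- fx_bath()
  cfg <- pool_config(fx_pool_mm(), 5)

  # zero response coefficients: base charges exactly
  sol0 <- bath$solute
  bath0 <- make_dipole_bath_system(
    solute_spec(sol0$coordinates, sol0$base_charges, 0),
    bath$solvent, bath$thermo)
  expect_equal(high_level_charges(bath0, cfg)$charges, sol0$base_charges)

  # isolated solute (no solvent): base charges exactly
  gas <- gas_phase_system(bath)
  cfg_gas <- bath_configuration(matrix(numeric(0), 3, 0))
  expect_equal(high_level_charges(gas, cfg_gas)$charges, sol0$base_charges)

  # responsive charges are neutral after re-neutralization
  q <- high_level_charges(bath, cfg)
  expect_equal(sum(q$charges), 0, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(q$charges, sol0$base_charges)))
})

test_that("high-level charges match a hand-evaluated Coulomb sum", {
  # 2-atom solute, single rotor at (0,3,0) pointing along -y
  tiny <- fx_tiny()
  u <- matrix(c(0, -1, 0), 3, 1)
  cfg <- bath_configuration(u)
  # direct pairwise evaluation: phi_i = k_e * m * u.(r_i - R)/|r_i - R|^3
  ke <- 332.0637; m <- 0.5
  r <- rbind(c(0, 0, 0), c(1.5, 0, 0)); R <- c(0, 3, 0)
  phi <- vapply(1:2, function(i) {
    d <- r[i, ] - R
    ke * m * sum(c(0, -1, 0) * d) / sum(d^2)^1.5
  }, 0)
  q_raw <- c(0.3, -0.3) + (-0.002) * phi
  q_exp <- q_raw - mean(q_raw)  # re-neutralized to net 0
  expect_equal(high_level_charges(tiny, cfg)$charges, q_exp, tolerance = 1e-12)
})

test_that("energies are deterministic and finite", {
  cfg <- pool_config(fx_pool_mm(), 3)
  e1 <- hybrid_energy(fx_bath(), cfg, 0.37)
  e2 <- hybrid_energy(fx_bath(), cfg, 0.37)
  expect_identical(e1, e2)
  expect_true(is.finite(e1))
  # convex combination of the two levels
  el <- hybrid_energy(fx_bath(), cfg, 0)
  eh <- hybrid_energy(fx_bath(), cfg, 1)
  expect_equal(hybrid_energy(fx_bath(), cfg, 0.37), 0.63 * el + 0.37 * eh,
               tolerance = 1e-12)
})

test_that("charge fluctuations on the shipped fixture stay below 0.03 e", {
  q <- fx_q_solv_star()
  expect_true(all(q$per_atom_std < 0.03))
  expect_gt(max(q$per_atom_std), 0)  # genuinely fluctuating
})

test_that("brute-force staged oracle recovers the harmonic closed form", {
  sys <- fx_harm()
  est <- brute_force_delta_a(sys, n_windows = 11, steps_per_window = 5000,
                             seed = 7, n_replicates = 4)
  expect_within_stderr(est, sys$analytic_delta_a)

  # identical levels: exactly zero (every work increment vanishes)
  same <- make_harmonic_pair(2, 2, 0, thermo_state_kT(0.6))
  est0 <- brute_force_delta_a(same, n_windows = 5, steps_per_window = 2000,
                              seed = 8, n_replicates = 4)
  expect_equal(est0$delta_a, 0, tolerance = 1e-9)

  # antisymmetry under exchanging the levels
  est_rev <- brute_force_delta_a(reverse_system(sys), n_windows = 11,
                                 steps_per_window = 5000, seed = 9,
                                 n_replicates = 4)
  expect_lt(abs(est$delta_a + est_rev$delta_a),
            3 * sqrt(est$stderr^2 + est_rev$stderr^2))
})

test_that("degenerate dipole-bath systems have zero free energy difference", {
  bath <- fx_bath()
  sol0 <- solute_spec(bath$solute$coordinates, bath$solute$base_charges, 0)
  degen <- make_dipole_bath_system(sol0, bath$solvent, bath$thermo)
  cfg <- pool_config(fx_pool_mm(), 1)
  expect_equal(hybrid_energy(degen, cfg, 0), hybrid_energy(degen, cfg, 1))
  # gas phase: levels differ only by the constant offset
  gas <- gas_phase_system(bath)
  cfg_gas <- bath_configuration(matrix(numeric(0), 3, 0))
  expect_equal(hybrid_energy(gas, cfg_gas, 1) - hybrid_energy(gas, cfg_gas, 0),
               gas$offset_high)
})
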