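test_that("hybrid energy is the exact convex combination", {
  sys <- fx_harm()
  expect_equal(hybrid_energy(sys, 0.9, 0), 0.5 * 1 * 0.9^2)
  expect_equal(hybrid_energy(sys, 0.9, 1), 0.5 * 4 * 0.4^2)
  expect_equal(hybrid_energy(sys, 0.9, 0.5),
               0.5 * (hybrid_energy(sys, 0.9, 0) + hybrid_energy(sys, 0.9, 1)))
  expect_error(hybrid_energy(sys, 0.9, 1.2), "lambda")
})

test_that("identical levels give exactly zero work", {
  same <- make_harmonic_pair(2, 2, 0, thermo_state_kT(0.6))
  pool <- sample_equilibrium(same, 0, sampler_settings(
    n_equil_steps = 100, n_prod_steps = 1000, save_every = 100,
    n_replicates = 1, seed = 4))
  wt <- run_switch_ensemble(same, pool, switch_settings(100, seed = 5))
  expect_equal(wt$final_work_kcal_mol, rep(0, length(pool)))

  # degenerate dipole bath (no charge response, same charges)
  bath <- fx_bath()
  sol0 <- solute_spec(bath$solute$coordinates, bath$solute$base_charges, 0)
  degen <- make_dipole_bath_system(sol0, bath$solvent, bath$thermo)
  poolb <- sample_equilibrium(degen, 0, sampler_settings(
    n_equil_steps = 50, n_prod_steps = 200, save_every = 100,
    n_replicates = 1, seed = 6))
  wtb <- run_switch_ensemble(degen, poolb, switch_settings(50, seed = 7))
  expect_equal(wtb$final_work_kcal_mol, rep(0, 2))
})

test_that("an instantaneous one-step switch accumulates the endpoint gap", {
  sys <- fx_harm()
  start <- pool_config(fx_harm_pool(), 10)
  rec <- run_switch(sys, start, switch_settings(1, seed = 9))
  x1 <- rec$final_config$x
  expect_equal(rec$final_work,
               0.5 * 4 * (x1 - 0.5)^2 - 0.5 * 1 * x1^2, tolerance = 1e-12)
  # trace starts at zero and ends at the final work
  expect_equal(rec$work_trace[1], 0)
  expect_equal(rec$work_trace[length(rec$work_trace)], rec$final_work)
})

test_that("work records and traces are consistent for multi-step switches", {
  sys <- fx_bath()
  start <- pool_config(fx_pool_mm(), 7)
  rec <- run_switch(sys, start, switch_settings(40, seed = 12))
  expect_length(rec$work_trace, 41)
  expect_equal(rec$work_trace[1], 0)
  expect_equal(rec$work_trace[41], rec$final_work)
  expect_true(all(is.finite(rec$work_trace)))
})

test_that("switch ensembles are deterministic and order-independent", {
  sys <- fx_harm()
  starts <- select_switch_starts(fx_harm_pool(), 400)  # 20 starts
  st <- switch_settings(100, seed = 31)
  w1 <- run_switch_ensemble(sys, starts, st)$final_work_kcal_mol
  w2 <- run_switch_ensemble(sys, starts, st)$final_work_kcal_mol
  expect_identical(w1, w2)
  # a permuted subset gives the same works for the same start indices:
  # each switch derives its seed from its position, so compare via rerun of
  # the identical pool (execution-order independence of the ensemble)
  w3 <- run_switch_ensemble(sys, starts[1:10], st)$final_work_kcal_mol
  expect_identical(w1[1:10], w3)
})

test_that("200 starts produce 200 work records in start order", {
  starts <- select_switch_starts(fx_harm_pool(), 40)
  wt <- run_switch_ensemble(fx_harm(), starts, switch_settings(200, seed = 17))
  expect_equal(nrow(wt), 200)
  expect_equal(wt$switch_id, 1:200)
  expect_equal(wt$start_replicate, starts$replicate)
})

test_that("the Jensen bound holds: JAR estimate never exceeds the mean work", {
  starts <- select_switch_starts(fx_harm_pool(), 80)
  for (N in c(50, 400)) {
    wt <- run_switch_ensemble(fx_harm(), starts,
                              switch_settings(N, seed = 40 + N))
    s <- as_work_sample(wt)
    expect_lte(jarzynski(s, n_boot = 0)$delta_a, mean(s$values))
  }
})

test_that("quasi-static switching converges to the analytic free energy", {
  sys <- fx_harm()
  starts <- select_switch_starts(fx_harm_pool(), 400)  # 20 slow switches
  wt <- run_switch_ensemble(sys, starts, switch_settings(20000, seed = 51))
  w <- wt$final_work_kcal_mol
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - sys$analytic_delta_a), 3 * se + 0.005)
  expect_lt(sd(w), 0.1)  # near-reversible: little dissipation spread
})

test_that("JAR bias on the harmonic pair decreases with switching length", {
  sys <- fx_harm()
  pool <- fx_harm_pool()
  bias <- sapply(c(100, 1000, 10000), function(N) {
    ests <- sapply(1:20, function(k) {
      idx <- seq((k - 1) * 20 + 1, k * 20)  # disjoint 20-start ensembles
      wt <- run_switch_ensemble(sys, pool[idx * 19],
                                switch_settings(N, seed = 600 + k))
      jarzynski(as_work_sample(wt), n_boot = 0)$delta_a
    })
    abs(mean(ests) - sys$analytic_delta_a)
  })
  expect_true(bias[2] < bias[1])
  expect_true(bias[3] < bias[2])
})

test_that("backward switches sample the reverse transformation", {
  sys <- fx_harm()
  startsb <- select_switch_starts(fx_harm_pool_hi(), 40)
  wtb <- run_switch_ensemble(sys, startsb,
                             switch_settings(2000, direction = "backward",
                                             seed = 71))
  expect_equal(unique(wtb$direction), "backward")
  # reverse-direction JAR estimates -delta A
  est <- jarzynski(work_sample(wtb$final_work_kcal_mol, "forward",
                               sys$thermo$beta), n_boot = 200, seed = 1)
  expect_lt(abs(est$delta_a - (-sys$analytic_delta_a)), 3 * est$stderr + 0.01)
})
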