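test_that("delta_delta_a implements the direct and indirect forms", {
  expect_equal(delta_delta_a(0.6, 0.6), 0)
  expect_equal(delta_delta_a(0.3, 0.6, correction = 0.5), 0.2)
  expect_equal(delta_delta_a(-1.1, 0.4), -1.5)
})

test_that("rmsd_q matches hand calculations and the triangle bound", {
  expect_equal(rmsd_q(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsd_q(0.2, 0), 0.2)
  expect_equal(rmsd_q(c(0.3, -0.1), c(0, 0)), sqrt(0.05))
  expect_error(rmsd_q(c(1, 2), c(1, 2, 3)), "lengths")
  set.seed(8)
  for (k in 1:20) {
    a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
    expect_lte(rmsd_q(a, c), rmsd_q(a, b) + rmsd_q(b, c) + 1e-12)
  }
})

test_that("differential dipole matches hand calculation and is origin-free", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  dd <- differential_dipole(c(0.2, -0.2), c(0.1, -0.1), xyz)
  expect_equal(dd$vector, c(-0.1, 0, 0))
  expect_equal(dd$magnitude_debye, 0.1 * 4.80320)
  # identical sets: zero vector
  expect_equal(differential_dipole(c(0.2, -0.2), c(0.2, -0.2), xyz)$vector,
               c(0, 0, 0))
  # rigid translation leaves the result unchanged when the net dq is zero
  shift <- sweep(xyz, 2, c(3, -2, 7), "+")
  dd2 <- differential_dipole(c(0.2, -0.2), c(0.1, -0.1), shift)
  expect_equal(dd2$vector, dd$vector, tolerance = 1e-12)
})

test_that("dipole angle covers aligned, orthogonal and antiparallel cases", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  qx <- c(-1, 1, 0)   # dipole along +x
  qy <- c(-1, 0, 1)   # dipole along +y
  expect_equal(dipole_angle(qx, qx, xyz), 0)
  expect_equal(dipole_angle(qx, qy, xyz), 90)
  expect_equal(dipole_angle(qx, -qx, xyz), 180)
  expect_error(dipole_angle(c(0, 0, 0), qx, xyz), "zero-magnitude")
})

test_that("first-shell counting uses the inclusive 3 Angstrom rule", {
  solute <- rbind(c(0, 0, 0))
  expect_equal(count_first_shell(rbind(c(2.5, 0, 0)), solute), 1L)
  expect_equal(count_first_shell(rbind(c(3.0, 0, 0)), solute), 1L)
  expect_equal(count_first_shell(rbind(c(3.01, 0, 0)), solute), 0L)
  # only heavy atoms anchor the shell
  solute2 <- rbind(c(0, 0, 0), c(2.8, 0, 0))
  site <- rbind(c(5.0, 0, 0))  # 2.2 A from atom 2 only
  expect_equal(count_first_shell(site, solute2), 1L)
  expect_equal(count_first_shell(site, solute2, heavy = c(TRUE, FALSE)), 0L)
})

test_that("delta_n_waters averages per-frame shell counts", {
  solute <- rbind(c(0, 0, 0))
  near <- rbind(c(1, 0, 0), c(2, 0, 0))   # 2 in shell
  far <- rbind(c(1, 0, 0), c(9, 0, 0))    # 1 in shell
  expect_equal(delta_n_waters(list(near, near), list(near, near), solute), 0)
  expect_equal(delta_n_waters(list(far, far), list(near, near), solute), -1)
  expect_equal(delta_n_waters(list(near, far), list(near, near), solute), -0.5)
  expect_error(delta_n_waters(list(), list(near), solute), "empty")
  # rotor-bath pools have frozen site positions: difference is exactly zero
  expect_equal(delta_n_waters(fx_pool_hi(), fx_pool_hi(),
                              fx_bath()$solute$coordinates), 0)
})

test_that("stokes_relaxation averages, subtracts the baseline and validates", {
  t <- seq(0, 10000)  # 10 ps at 1 fs
  # constant series: shifted identically zero; default window = last 2 ps
  s <- stokes_relaxation(matrix(5, length(t), 3), t)
  expect_equal(s$baseline, 5)
  expect_equal(s$shifted, rep(0, length(t)))
  expect_equal(s$n_baseline_entries, 2001L)  # 8-10 ps inclusive
  # two mirrored trajectories cancel
  f <- exp(-t / 800)
  s2 <- stokes_relaxation(cbind(f, -f), t)
  expect_equal(s2$mean_gap, rep(0, length(t)))
  expect_error(stokes_relaxation(cbind(f), t, baseline_window = c(2e4, 3e4)),
               "window")
  expect_error(stokes_relaxation(cbind(f), rev(t)), "increasing")
})

test_that("the mono-exponential fit recovers noiseless parameters exactly", {
  t <- seq(0, 8000, by = 4)
  y <- 4 * exp(-t / 1000)
  s <- stokes_relaxation(matrix(y + 0, ncol = 1), t,
                         baseline_window = c(7000, 8000))
  # re-add the (tiny) baseline the window subtracts so the target is exact
  s$shifted <- y
  fit <- fit_mono_exponential(s, discard = 500)
  expect_equal(fit$amplitude, 4, tolerance = 1e-6)
  expect_equal(fit$tau, 1000, tolerance = 1e-3)
  expect_lt(fit$fit_rss, 1e-10)
})

test_that("the 0.5 ps discard suppresses a fast second exponential", {
  t <- seq(0, 10000, by = 5)
  y <- 10 * exp(-t / 100) + 4 * exp(-t / 1000)
  s <- stokes_relaxation(matrix(y, ncol = 1), t, baseline_window = c(9000, 10000))
  s$shifted <- y
  fit <- fit_mono_exponential(s, discard = 500)
  expect_lt(abs(fit$tau - 1000) / 1000, 0.10)
})

test_that("noisy ensemble averages still recover the decay within 5 percent", {
  t <- seq(0, 10000, by = 10)
  set.seed(21)
  gaps <- vapply(seq_len(800), function(i)
    12 * exp(-t / 900) + rnorm(length(t), sd = 0.1) * sqrt(800 / 8),
    numeric(length(t)))
  # per-trajectory noise chosen so the 800-average has sd ~0.1/sqrt(8)
  s <- stokes_relaxation(gaps, t)
  fit <- fit_mono_exponential(s, discard = 500)
  expect_lt(abs(fit$amplitude - 12) / 12, 0.05)
  expect_lt(abs(fit$tau - 900) / 900, 0.05)
})

test_that("degenerate shifted series raise a fit error", {
  t <- seq(0, 5000, by = 10)
  s <- stokes_relaxation(matrix(-exp(-t / 500), ncol = 1), t,
                         baseline_window = c(4500, 5000))
  s$shifted <- -exp(-t / 500)
  expect_error(fit_mono_exponential(s), "fit-degenerate")
  s$shifted <- rep(0.5, length(t))
  expect_error(fit_mono_exponential(s, discard = 4990), "fewer than 10")
})

test_that("evaluate_fit_at decays monotonically from the amplitude", {
  fit <- list(amplitude = 10.5, tau = 1000)
  expect_equal(evaluate_fit_at(fit, 0), 10.5)
  expect_equal(evaluate_fit_at(fit, 2000), 10.5 * exp(-2))
  expect_equal(evaluate_fit_at(fit, 1e9), 0, tolerance = 1e-12)
  ts <- seq(0, 5000, by = 100)
  expect_true(all(diff(evaluate_fit_at(fit, ts)) < 0))
})

test_that("equilibrium high-level starts show no relaxation transient", {
  starts <- select_switch_starts(fx_pool_hi(), 20)
  se <- simulate_stokes_ensemble(fx_bath(), starts, length_fs = 2000,
                                 record_every = 20, seed = 91)
  ss <- stokes_relaxation(se$gaps, se$times)
  # per-time standard error across trajectories; allow rare 3-sigma
  # excursions among the ~100 correlated time points
  stderr_t <- apply(se$gaps, 1, sd) / sqrt(ncol(se$gaps))
  expect_lt(mean(abs(ss$shifted) > 3 * stderr_t), 0.1)
  expect_lt(max(abs(ss$shifted)), 1)
})

test_that("mad_and_spread summarizes absolute deviations", {
  s <- mad_and_spread(c(0.1, -0.2, 0.3))
  expect_equal(s$mad, 0.2)
  expect_equal(s$spread_min, 0.1)
  expect_equal(s$spread_max, 0.3)
  z <- mad_and_spread(c(0, 0))
  expect_equal(c(z$mad, z$spread_min, z$spread_max), c(0, 0, 0))
  one <- mad_and_spread(-1.8)
  expect_equal(c(one$mad, one$spread_min, one$spread_max), c(1.8, 1.8, 1.8))
  expect_error(mad_and_spread(numeric(0)), "empty")
})
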