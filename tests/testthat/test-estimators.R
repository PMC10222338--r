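test_that("jarzynski handles degenerate samples exactly", {
  b <- 1.5
  expect_equal(jarzynski(work_sample(rep(2.5, 7), "forward", b), n_boot = 0)$delta_a,
               2.5)
  expect_equal(jarzynski(work_sample(c(0, 0, 0), "forward", b), n_boot = 0)$delta_a,
               0)
  expect_error(jarzynski(work_sample(numeric(0), "forward", b)), "empty")
  expect_error(work_sample(c(1, NA), "forward", b), "finite")
})

test_that("jarzynski recovers the Gaussian-work closed form mu - beta sigma^2/2", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(314)
  w <- rnorm(2e5, mean = 2.0, sd = sqrt(0.5))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  est <- jarzynski(work_sample(w, "forward", beta = 1), n_boot = 100, seed = 2)
  expect_lt(abs(est$delta_a - 1.75), 3 * est$stderr)
  expect_gt(est$stderr, 0)
})

test_that("jarzynski is stable against overflow-scale work values", {
  w <- c(1e4, 1e4 + 1, 1e4 + 2)
  est <- jarzynski(work_sample(w, "forward", beta = 1), n_boot = 0)
  expect_true(is.finite(est$delta_a))
  expect_lt(est$delta_a, 1e4 + 1)  # dominated by the smallest work value
})

test_that("work_sigma is the n-1 sample standard deviation", {
  expect_equal(work_sigma(c(1, 1, 1)), 0)
  expect_equal(work_sigma(c(0, 2)), sqrt(2))
  w <- c(0.3, 1.7, -2.2, 0.9)
  expect_equal(work_sigma(w + 5), work_sigma(w))
  expect_error(work_sigma(1.5), "at least 2")
})

test_that("two_sided solves the Bennett condition on degenerate samples", {
  b <- 1
  f <- work_sample(rep(1, 20), "forward", b)
  r <- work_sample(rep(0.5, 20), "backward", b)
  # point-mass histograms are disjoint, so the overlap warning also fires
  est <- suppressWarnings(two_sided(f, r, n_boot = 0))
  expect_equal(est$delta_a, 0.25, tolerance = 1e-7)

  # mirror-symmetric samples about zero: delta A = 0
  v <- c(-0.4, -0.1, 0.2, 0.9)
  est0 <- two_sided(work_sample(v, "forward", b),
                    work_sample(v, "backward", b), n_boot = 0)
  expect_equal(est0$delta_a, 0, tolerance = 1e-7)
  expect_error(two_sided(f, work_sample(1, "backward", 2)), "beta")
})

test_that("two_sided is antisymmetric under swapping the samples", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(99)
  wf <- rnorm(300, 1.2, 0.8)
  wr <- rnorm(280, -0.4, 0.9)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  b <- 1.4
  a1 <- two_sided(work_sample(wf, "forward", b),
                  work_sample(wr, "backward", b), n_boot = 0)$delta_a
  a2 <- two_sided(work_sample(wr, "forward", b),
                  work_sample(wf, "backward", b), n_boot = 0)$delta_a
  expect_equal(a1, -a2, tolerance = 1e-6)
})

test_that("two_sided asymptotic and bootstrap errors agree within a factor of 2", {
  # well-overlapped Crooks-consistent Gaussian samples
  beta <- 1; sig <- 0.8; dA <- 0.7
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(123)
  wf <- rnorm(400, dA + beta * sig^2 / 2, sig)
  wr <- rnorm(400, -dA + beta * sig^2 / 2, sig)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  est <- two_sided(work_sample(wf, "forward", beta),
                   work_sample(wr, "backward", beta), n_boot = 200, seed = 5)
  ratio <- est$stderr / est$diagnostics$stderr_boot
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  expect_lt(abs(est$delta_a - dA), 3 * est$stderr)
  expect_gt(est$diagnostics$histogram_overlap, 0.5)
})

test_that("disjoint work histograms trigger the overlap warning", {
  f <- work_sample(rnorm(50, 100, 0.1), "forward", 1)
  r <- work_sample(rnorm(50, 100, 0.1), "backward", 1)  # -W_R near -100
  expect_warning(est <- two_sided(f, r, n_boot = 0), "overlap")
  expect_true(est$diagnostics$overlap_warning)
  expect_equal(est$diagnostics$histogram_overlap, 0)
  expect_gt(est$stderr, 1)
})

test_that("histogram overlap is 1 for identical samples and bounded in [0,1]", {
  x <- rnorm(500)
  expect_equal(histogram_overlap(x, x), 1)
  ov <- histogram_overlap(rnorm(200), rnorm(200, 1))
  expect_gte(ov, 0); expect_lte(ov, 1)
})

test_that("staged BAR is exact for identical states and recovers the ladder sum", {
  # three identical states: every sample has the same reduced energy at all
  # states, so every stage contributes zero
  u <- matrix(rep(rnorm(20), 3), 20, 3)
  u_list <- list(u, u, u)
  est <- staged_bar(u_list, lambdas = c(0, 0.5, 1), beta = 1)
  expect_equal(est$delta_a, 0, tolerance = 1e-7)
  expect_error(staged_bar(list(u), lambdas = 0, beta = 1), "2 states")
  expect_error(staged_bar(list(u[, 1:2], u[, 1:2], u[, 1:2]),
                          lambdas = c(0, 0.5, 1), beta = 1), "re-evaluations")
})

test_that("staged BAR over 11 harmonic windows matches the closed form", {
  sys <- fx_harm()
  staged <- sample_staged(sys, seq(0, 1, length.out = 11), sampler_settings(
    n_equil_steps = 1000, n_prod_steps = 6000, save_every = 60,
    n_replicates = 8, seed = 77))
  est <- staged_bar(staged)
  expect_equal(est$method, "BAR-staged")
  expect_within_stderr(est, sys$analytic_delta_a)
  # replicate-propagated error is positive and sane
  expect_gt(est$stderr, 0)
  expect_lt(est$stderr, 0.05)
})

test_that("crooks slope recovers beta on consistent Gaussian distributions", {
  beta <- 2; sig <- 0.7; dA <- 0.3
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(42)
  wf <- rnorm(2000, dA + beta * sig^2 / 2, sig)
  wr <- rnorm(2000, -dA + beta * sig^2 / 2, sig)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s_hist <- crooks_slope(wf, wr, bins = 50)
  s_ml <- crooks_slope(wf, wr, method = "logistic")
  expect_lt(abs(s_hist / beta - 1), 0.15)
  expect_lt(abs(s_ml / beta - 1), 0.10)
})
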