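#' Work sample
#'
#' A directed collection of non-equilibrium work values at a stated inverse
#' temperature, the input type of all free energy estimators.
#'
#' @param values Work values (kcal/mol); finite, non-empty for estimation.
#' @param direction `"forward"` or `"backward"`.
#' @param beta Inverse temperature (mol/kcal).
#' @param label Optional label.
#' @return An object of class `work_sample`.
#' @export
work_sample <- function(values, direction = c("forward", "backward"),
                        beta, label = NULL) {
  direction <- match.arg(direction)
  check_number(beta, "beta", positive = TRUE)
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stopf("estimation error: work values must be finite")
  structure(list(values = values, direction = direction, beta = beta,
                 label = label),
            class = "work_sample")
}

#' Convert a work table to a work sample
#'
#' @param x A `work_table` from [run_switch_ensemble()] (or a data frame with
#'   column `final_work_kcal_mol`).
#' @param beta Inverse temperature; defaults to the table's `beta` attribute.
#' @param label Optional label.
#' @return A [work_sample()].
#' @export
as_work_sample <- function(x, beta = attr(x, "beta"), label = NULL) {
  if (is.null(beta)) stopf("estimation error: `beta` is required")
  direction <- if (nrow(x) > 0 && all(x$direction == "backward")) "backward" else "forward"
  work_sample(x$final_work_kcal_mol, direction = direction, beta = beta,
              label = label)
}

new_estimate <- function(delta_a, stderr, method, n_forward, n_backward,
                         diagnostics = list()) {
  structure(
    list(delta_a = delta_a, stderr = stderr, method = method,
         n_forward = n_forward, n_backward = n_backward,
         diagnostics = diagnostics),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate %s> delta A = %.4f +/- %.4f kcal/mol (nF = %d, nB = %d)\n",
              x$method, x$delta_a, x$stderr, x$n_forward, x$n_backward))
  invisible(x)
}

# -(1/beta) * log(mean(exp(-beta * w))), overflow-free
log_mean_exp_neg <- function(bw) {
  m <- min(bw)
  m + -log(mean(exp(-(bw - m))))
}

#' Jarzynski free energy estimator
#'
#' One-sided exponential work average,
#' \eqn{\Delta A = -k_B T \ln \langle \exp(-\beta W) \rangle}, computed with
#' a log-sum-exp-stable reduction.  The standard error is obtained by a
#' seeded bootstrap over the work values (the exponential average's
#' asymptotic variance is unreliable at small sample sizes).
#'
#' @param sample A forward-direction [work_sample()].
#' @param n_boot Bootstrap resamples for the standard error.
#' @param seed Bootstrap seed.
#' @return A `free_energy_estimate` with method `"JAR"`; diagnostics carry
#'   \eqn{\sigma_W} and the mean work.
#' @examples
#' s <- work_sample(c(1, 1, 1), "forward", beta = 1)
#' jarzynski(s)$delta_a  # exactly 1
#' @export
jarzynski <- function(sample, n_boot = 1000, seed = 1) {
  stopifnot(inherits(sample, "work_sample"))
  if (length(sample$values) == 0L)
    stopf("estimation error: empty work sample")
  if (sample$direction != "forward")
    stopf("estimation error: jarzynski() requires a forward-direction sample")
  beta <- sample$beta
  w <- sample$values
  est <- log_mean_exp_neg(beta * w) / beta
  se <- 0
  if (length(w) > 1L && n_boot > 0) {
    rs <- boot_rng(seed, n_boot, length(w))
    bvals <- vapply(seq_len(n_boot), function(b)
      log_mean_exp_neg(beta * w[rs[, b]]) / beta, 0)
    se <- sd(bvals)
  }
  new_estimate(est, se, "JAR", length(w), 0L,
               diagnostics = list(
                 sigma_w_forward = if (length(w) > 1) sd(w) else NA_real_,
                 mean_w_forward = mean(w)))
}

# deterministic bootstrap index matrix (independent of R's global RNG)
boot_rng <- function(seed, n_boot, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
}

#' Sample standard deviation of work values
#'
#' \eqn{\sigma_W} (n-1 denominator), a sensitive indicator of whether
#' one-sided estimates can be expected to converge.
#'
#' @param sample A [work_sample()] (or numeric vector) with >= 2 values.
#' @return \eqn{\sigma_W} in kcal/mol.
#' @export
work_sigma <- function(sample) {
  w <- if (inherits(sample, "work_sample")) sample$values else as.numeric(sample)
  if (length(w) < 2L)
    stopf("estimation error: need at least 2 work values for sigma_W")
  sd(w)
}

# Bennett implicit function: increasing in dA, root is the estimate
bar_objective <- function(dA, wf, wr, beta, M) {
  sum(plogis(-(M + beta * (wf - dA)))) -
    sum(plogis(-(-M + beta * (wr + dA))))
}

#' Two-sided (Crooks/Bennett) free energy estimator
#'
#' Solves the Bennett acceptance-ratio self-consistency condition on the
#' forward works and the negated backward works -- the maximum-likelihood
#' estimator consistent with the Crooks fluctuation theorem relating the two
#' work distributions.  Diagnostics include the work standard deviations,
#' the histogram overlap of \eqn{P_F(W)} and \eqn{P_R(-W)}, and the fitted
#' Crooks slope of \eqn{\ln[P_F(W)/P_R(-W)]} against \eqn{W} (which equals
#' \eqn{\beta} when the two distributions are consistent).
#'
#' @param forward Forward-direction [work_sample()].
#' @param backward Backward-direction [work_sample()] (same \eqn{\beta}).
#' @param tol Convergence tolerance on \eqn{\Delta A} (kcal/mol).
#' @param n_boot Bootstrap resamples for the cross-check standard error.
#' @param seed Bootstrap seed.
#' @return A `free_energy_estimate` with method `"CRO"`; `stderr` is the
#'   asymptotic (Bennett) standard error, `diagnostics$stderr_boot` the
#'   bootstrap cross-check.  If the work histograms do not overlap the
#'   estimate is returned with `diagnostics$overlap_warning = TRUE` and the
#'   standard error inflated to the larger of the two.
#' @examples
#' f <- work_sample(rep(1, 10), "forward", beta = 1)
#' b <- work_sample(rep(0.5, 10), "backward", beta = 1)
#' two_sided(f, b)$delta_a  # 0.25
#' @export
two_sided <- function(forward, backward, tol = 1e-8, n_boot = 200, seed = 1) {
  stopifnot(inherits(forward, "work_sample"), inherits(backward, "work_sample"))
  if (length(forward$values) == 0L || length(backward$values) == 0L)
    stopf("estimation error: both samples must be non-empty")
  if (abs(forward$beta - backward$beta) > 1e-12)
    stopf("estimation error: forward and backward samples have different beta")
  beta <- forward$beta
  wf <- forward$values
  wr <- backward$values
  est <- bar_solve(wf, wr, beta, tol)

  nf <- length(wf); nr <- length(wr)
  M <- log(nf / nr)
  f <- plogis(-(M + beta * (wf - est)))
  g <- plogis(-(-M + beta * (wr + est)))
  var_red <- (mean(f^2) / mean(f)^2 - 1) / nf +
    (mean(g^2) / mean(g)^2 - 1) / nr
  se_asym <- sqrt(max(var_red, 0)) / beta

  se_boot <- NA_real_
  if (n_boot > 0 && nf > 1 && nr > 1) {
    rf <- boot_rng(child_seed(seed, "bar-boot-f"), n_boot, nf)
    rb <- boot_rng(child_seed(seed, "bar-boot-b"), n_boot, nr)
    bvals <- vapply(seq_len(n_boot), function(b)
      bar_solve(wf[rf[, b]], wr[rb[, b]], beta, tol), 0)
    se_boot <- sd(bvals)
  }

  ov <- histogram_overlap(wf, -wr)
  slope <- tryCatch(crooks_slope(wf, wr), error = function(e) NA_real_)
  diag <- list(
    sigma_w_forward = if (nf > 1) sd(wf) else NA_real_,
    sigma_w_backward = if (nr > 1) sd(wr) else NA_real_,
    histogram_overlap = ov, crooks_slope = slope,
    stderr_boot = se_boot, overlap_warning = FALSE
  )
  se <- se_asym
  if (ov == 0) {
    diag$overlap_warning <- TRUE
    se <- max(se_asym, se_boot, abs(mean(wf) + mean(wr)) / 2, na.rm = TRUE)
    warning("no overlap between forward and backward work histograms; standard error inflated",
            call. = FALSE)
  }
  new_estimate(est, se, "CRO", nf, nr, diagnostics = diag)
}

bar_solve <- function(wf, wr, beta, tol = 1e-8) {
  nf <- length(wf); nr <- length(wr)
  M <- log(nf / nr)
  lo <- min(c(wf, -wr)) - 1
  hi <- max(c(wf, -wr)) + 1
  # expand the bracket if needed (degenerate but possible for tiny samples)
  while (bar_objective(lo, wf, wr, beta, M) > 0) lo <- lo - (hi - lo)
  while (bar_objective(hi, wf, wr, beta, M) < 0) hi <- hi + (hi - lo)
  uniroot(bar_objective, c(lo, hi), wf = wf, wr = wr, beta = beta, M = M,
          tol = tol)$root
}

# shared-bin histogram masses for two samples (Freedman-Diaconis width)
shared_histogram <- function(a, b, bins = NULL) {
  all <- c(a, b)
  rng <- range(all)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  if (is.null(bins)) {
    iqr <- stats::IQR(all)
    h <- 2 * iqr / length(all)^(1 / 3)
    bins <- if (h > 0) max(1L, ceiling(diff(rng) / h)) else 30L
    bins <- min(bins, 1000L)
  }
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  ca <- tabulate(findInterval(a, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  cb <- tabulate(findInterval(b, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  list(breaks = brk, mids = (brk[-1] + brk[-length(brk)]) / 2,
       pa = ca / length(a), pb = cb / length(b),
       width = diff(brk)[1])
}

#' Histogram overlap of forward and mirrored backward work distributions
#'
#' The integral of \eqn{\min(\hat P_F(W), \hat P_R(-W))} with shared binning
#' (Freedman-Diaconis by default); 1 for identical distributions, 0 for
#' disjoint ones.
#'
#' @param wf Forward work values; or a forward [work_sample()].
#' @param w_neg_r Negated backward work values (i.e. \eqn{-W_R}); or a
#'   backward [work_sample()] whose values are negated internally.
#' @param bins Optional fixed number of bins.
#' @return Overlap fraction in `[0, 1]`.
#' @export
histogram_overlap <- function(wf, w_neg_r, bins = NULL) {
  if (inherits(wf, "work_sample")) wf <- wf$values
  if (inherits(w_neg_r, "work_sample")) w_neg_r <- -w_neg_r$values
  h <- shared_histogram(wf, w_neg_r, bins)
  sum(pmin(h$pa, h$pb))
}

#' Crooks-slope diagnostic
#'
#' Regression slope of \eqn{\ln[\hat P_F(W) / \hat P_R(-W)]} against
#' \eqn{W} over the histogram-overlap region.  The fluctuation theorem
#' implies a slope of \eqn{\beta}, so departures flag inconsistent or
#' non-overlapping work distributions.
#'
#' Two estimators of the same line are provided.  `"histogram"` bins both
#' samples on a shared grid and regresses the log count ratio on the bin
#' centers, weighting bins by smoothed (normal-approximation) expected
#' counts -- weighting by the noisy observed counts would correlate the
#' weights with the errors and attenuate the slope -- and applying the
#' first-order Jensen correction for the log of small counts.
#' `"logistic"` fits the identical log-density-ratio line by logistic
#' regression of sample membership on the work value (the
#' maximum-likelihood estimator of the ratio, free of binning noise);
#' prefer it for quantitative checks at small sample sizes.
#'
#' @param forward Forward work values or [work_sample()].
#' @param backward Backward work values or [work_sample()].
#' @param bins Number of shared histogram bins (default 50).
#' @param method `"histogram"` or `"logistic"`.
#' @return Fitted slope (mol/kcal).
#' @export
crooks_slope <- function(forward, backward, bins = 50,
                         method = c("histogram", "logistic")) {
  method <- match.arg(method)
  wf <- if (inherits(forward, "work_sample")) forward$values else forward
  wr <- if (inherits(backward, "work_sample")) backward$values else backward
  wnr <- -wr
  if (method == "logistic") {
    x <- c(wf, wnr)
    lab <- c(rep(1L, length(wf)), rep(0L, length(wnr)))
    fit <- suppressWarnings(glm(lab ~ x, family = stats::binomial()))
    return(unname(coef(fit)[2]))
  }
  h <- shared_histogram(wf, wnr, bins)
  ca <- h$pa * length(wf)
  cb <- h$pb * length(wnr)
  ea <- length(wf) * h$width * stats::dnorm(h$mids, mean(wf), sd(wf))
  eb <- length(wnr) * h$width * stats::dnorm(h$mids, mean(wnr), sd(wnr))
  ok <- ca > 0 & cb > 0
  if (sum(ok) < 3L)
    stopf("estimation error: fewer than 3 histogram bins with both samples present")
  y <- log(ca[ok] / cb[ok]) + log(length(wnr) / length(wf)) +
    1 / (2 * ca[ok]) - 1 / (2 * cb[ok])
  w <- 1 / (1 / ea[ok] + 1 / eb[ok])
  unname(coef(lm(y ~ h$mids[ok], weights = w))[2])
}

#' Staged BAR over a ladder of intermediate states
#'
#' Pairwise two-sided (Bennett) estimation between neighboring states on the
#' potential-energy differences of each state's samples, summed over stages.
#' With replicate provenance the standard error is the standard deviation of
#' the replicate-wise totals divided by \eqn{\sqrt{R}} (Gaussian error
#' propagation over independent repetitions); otherwise the per-stage
#' asymptotic variances are propagated.
#'
#' @param energies A `staged_energies` object from [sample_staged()], or a
#'   list of per-state reduced-energy matrices (rows = samples from that
#'   state, columns = all states).
#' @param lambdas Coupling values (required when `energies` is a bare list).
#' @param beta Inverse temperature (required when `energies` is a bare
#'   list).
#' @param replicates Optional list of per-state replicate label vectors.
#' @return A `free_energy_estimate` with method `"BAR-staged"`; diagnostics
#'   list the per-stage estimates and overlaps.
#' @export
staged_bar <- function(energies, lambdas = NULL, beta = NULL,
                       replicates = NULL) {
  if (inherits(energies, "staged_energies")) {
    lambdas <- energies$lambdas
    beta <- energies$beta
    replicates <- energies$replicates
    u_list <- energies$u
  } else {
    u_list <- energies
    if (is.null(lambdas) || is.null(beta))
      stopf("input error: `lambdas` and `beta` are required with a bare energy list")
  }
  K <- length(u_list)
  if (K < 2L) stopf("input error: need at least 2 states")
  for (s in seq_len(K))
    if (ncol(u_list[[s]]) != K)
      stopf("input error: state %d samples lack re-evaluations at all %d states", s, K)

  stage_est <- function(rows) {
    tot <- 0; var_tot <- 0; stages <- vector("list", K - 1L)
    for (s in seq_len(K - 1L)) {
      us <- u_list[[s]]; un <- u_list[[s + 1L]]
      is <- if (is.null(rows)) seq_len(nrow(us)) else which(rows[[s]])
      in1 <- if (is.null(rows)) seq_len(nrow(un)) else which(rows[[s + 1L]])
      wf <- (us[is, s + 1L] - us[is, s]) / beta
      wr <- (un[in1, s] - un[in1, s + 1L]) / beta
      est <- two_sided(work_sample(wf, "forward", beta),
                       work_sample(wr, "backward", beta), n_boot = 0)
      tot <- tot + est$delta_a
      var_tot <- var_tot + est$stderr^2
      stages[[s]] <- list(from = lambdas[s], to = lambdas[s + 1L],
                          delta_a = est$delta_a, stderr = est$stderr,
                          histogram_overlap = est$diagnostics$histogram_overlap)
    }
    list(total = tot, var = var_tot, stages = stages)
  }

  full <- stage_est(NULL)
  se <- sqrt(full$var)
  rep_totals <- NULL
  if (!is.null(replicates) && length(unique(replicates[[1]])) > 1L) {
    reps <- sort(unique(replicates[[1]]))
    rep_totals <- vapply(reps, function(r) {
      rows <- lapply(replicates, function(v) v == r)
      stage_est(rows)$total
    }, 0)
    se <- sd(rep_totals) / sqrt(length(reps))
  }
  n_tot <- sum(vapply(u_list, nrow, 0L))
  new_estimate(full$total, se, "BAR-staged", n_tot, n_tot,
               diagnostics = list(stages = full$stages,
                                  replicate_totals = rep_totals,
                                  lambdas = lambdas))
}
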