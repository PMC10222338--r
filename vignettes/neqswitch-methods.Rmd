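---
title: "Methods: non-equilibrium work switching between two levels of theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-equilibrium work switching between two levels of theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Many free energy questions require the system of interest to be described at
a "high" level of theory (e.g. a semi-empirical QM/MM Hamiltonian with
environment-responsive charges) that is too expensive for the long alchemical
simulations that answer them.  The standard workaround is an indirect
thermodynamic cycle: run the alchemistry at a cheap "low" level (a
fixed-charge force field) and correct the result with the free energy
difference between the two levels,
$\Delta A_{\mathrm{low}\to\mathrm{high}}$.  `neqswitch` implements the
non-equilibrium work (NEW) route to that correction: many short driven
simulations switch the Hamiltonian from the low to the high level while
accumulating mechanical work, and estimators based on the work fluctuation
theorems turn the work sample into a free energy difference.

The package deliberately operates on *toy* dual-level systems with exact or
brute-force oracles, so that every estimator and every protocol choice can be
validated end to end.  It is a methods laboratory, not a production MD code.

# Hybrid energy, schedules and work accumulation

The switching engine propagates Langevin dynamics on the hybrid energy

$$U(\lambda) = (1-\lambda)\,U_{\mathrm{low}} + \lambda\,U_{\mathrm{high}},$$

with the coupling parameter driven by a schedule.  The standard linear
protocol increments $\lambda_i = i/N_{\mathrm{switch}}$; stepwise-linear
protocols (presets `L2-1`, `L3-1`, `L3-2`) switch quickly through an initial
stage (to 0.35 within the first 10% of the path) and more slowly afterwards,
the idea being to give the slow solvent-reorientation process as much of the
switching time as possible.  Schedules are defined piecewise-linearly in
*time*, so stage boundaries need not coincide with integer steps;
`lambda_at()` evaluates the path exactly at step times.

After each dynamics step (run at the pre-step $\lambda$), the work increment

$$W(t+\delta t) = W(t) + U(x_{t+\delta t}, \lambda_{t+\delta t})
                       - U(x_{t+\delta t}, \lambda_{t})$$

is accumulated, i.e. both energies are evaluated at the *post-step*
coordinates.  $\lambda_0 = 0$ holds at the starting configuration and the
first increment occurs at step 1.  The thermostat remains active during
switches (a flagless design choice: the friction used for equilibrium
sampling also acts during driven dynamics).  Starting configurations and
velocities are taken from saved restart records of equilibrium runs --
velocities are *not* resampled at the start of a switch.

# Estimators

* `jarzynski()` -- the one-sided exponential estimator
  $\Delta A = -k_BT \ln \langle e^{-\beta W}\rangle$, computed through a
  log-sum-exp-stable reduction so it cannot overflow.  Its standard error
  comes from a seeded bootstrap (default 1000 resamples): the asymptotic
  variance of an exponential average is unreliable at realistic sample
  sizes.
* `two_sided()` -- the Bennett acceptance-ratio (BAR) estimator, the
  maximum-likelihood solution consistent with the Crooks fluctuation theorem
  relating forward and backward work distributions.  The self-consistency
  equation is solved by safeguarded root bracketing to a configurable
  tolerance (default $10^{-8}$ kcal/mol).  The asymptotic (Bennett) standard
  error is reported, with a bootstrap cross-check in the diagnostics.  If
  the two work histograms do not overlap at all, the estimate is still
  returned, flagged, with an inflated standard error.
* `staged_bar()` -- pairwise BAR between neighboring states of a coupling
  ladder, summed over stages.  With replicate provenance (the default; 8
  independent repetitions) the standard error is the standard deviation of
  the replicate totals over $\sqrt{R}$, which remains honest even when
  samples within a replicate are time-correlated.
* Diagnostics: `work_sigma()` ($\sigma_W$, the convergence indicator for
  one-sided estimates), `histogram_overlap()` (integral of the pointwise
  minimum of $\hat P_F(W)$ and $\hat P_R(-W)$ on shared Freedman--Diaconis
  bins), and `crooks_slope()` (the fitted slope of
  $\ln[\hat P_F(W)/\hat P_R(-W)]$ against $W$, which must equal $\beta$).

Two numerical choices in `crooks_slope()` deserve a note.  The histogram
variant weights bins by *smoothed* (normal-approximation) expected counts:
weighting by the observed counts correlates the weights with the bin noise
and systematically attenuates the slope.  It also applies the first-order
Jensen correction $+1/(2c_a) - 1/(2c_b)$ for the bias of the log of small
counts.  Even so, the histogram regression is noisy at a few hundred
switches per direction, so a `"logistic"` method fits the same
log-density-ratio line by logistic regression of sample membership on the
work value -- the maximum-likelihood estimator of the ratio, free of binning
-- and is the variant used for quantitative calibration checks.

# Toy model systems

## Harmonic pair

A single 1-D particle with $U_{\mathrm{low}} = k_l x^2/2$ and
$U_{\mathrm{high}} = k_h (x-x_0)^2/2$ has the closed form
$\Delta A = (k_BT/2)\ln(k_h/k_l)$, independent of the offset.  It is the
exact oracle behind every estimator test.  Defaults: mass 12 amu, friction
5 ps$^{-1}$, timestep 1 fs.  For fluctuation-theorem calibrations the tests
use a heavier particle (100 amu) and a 0.5 fs timestep: the discrete
integrator satisfies the work theorems only up to $O((\omega\,\delta t)^2)$,
and those settings push that error well below the statistical resolution.

## Polarizable solute in a dipolar rotor bath

The dipole-bath system stands in for a solvated solute described at two
levels that differ primarily in the solute's charge distribution:

* a rigid solute (fixed coordinates) with base charges $q_i^0$;
* a solvent of point-dipole rotors at fixed positions whose orientations
  evolve by rotational Langevin (BAOAB) dynamics;
* a low level with fixed charges, and a high level whose charges respond
  linearly to the local electrostatic potential $\phi_i$ from the rotors,
  $q_i = q_i^0 + \kappa_i\,\phi_i$, re-neutralized to the declared net
  charge by uniform subtraction of the excess.

With $\kappa_i < 0$ the solute polarizes *with* the reaction field: the
positive atoms sit in a negative potential and become more positive, so the
solute dipole is enhanced in solution relative to the gas phase -- the
qualitative behavior of a semi-empirical solute among fixed-charge waters.
The instantaneous high-level charges fluctuate configuration by
configuration (the Mulliken-like behavior the hybrid-charge strategy
exploits), while their ensemble averages are well defined.

The shipped fixture `polar_solute_system()` (also available as the YAML file
`polar-solute-64rotors.yaml`) uses a four-atom solute with a permanent
dipole, $\kappa = -0.0015$ e per (kcal/mol/e), and 64 rotors of dipole
moment 0.49 e·Å (≈ a water dipole) on two spherical shells at 4.0 and
6.5 Å.  These constants were fixed once so that the fixture has the
statistical structure the method assumes: per-atom charge fluctuations well
below 0.03 e about their means, average high-level charges that differ
appreciably (≈ 0.15–0.2 e) from the base charges, and a solvent whose
reorientational relaxation after a charge jump decays on two timescales.

The rotor inertia (600 amu·Å²) and friction (2000 ps$^{-1}$) place the slow
reorientational relaxation near 1 ps at a 1 fs timestep.  Both values are
larger than any single water-like molecule would have; they are effective
parameters.  A discrete-time Langevin integrator cannot make small, weakly
damped rotors diffuse arbitrarily slowly (the effective rotational diffusion
is bounded below by $k_BT\,\delta t/(2I)$), so slow collective water-like
relaxation is emulated by slow single-rotor diffusion instead of by
hydrogen-bond network dynamics.  The fast sub-0.5-ps component arises from
libration of the strongly coupled inner-shell rotors; the slow component
from rotational diffusion of the whole bath.

Deliberate omissions, and what they imply about the tests: rotors do not
interact with each other (no dielectric cooperativity), rotor positions and
the solute geometry are frozen (so translational solvent structure,
first-shell *exchange*, and conformational effects are absent -- the
first-shell counting operations are therefore exercised on explicit
coordinate frames, and on the fixture the mean shell-count difference
between levels is exactly zero), intra-solute electrostatics is treated as
part of the constant level offset, and there are no periodic boundaries or
long-range corrections.  Passing tests therefore demonstrate the
correctness and calibration of the estimators, protocols and analyses --
not that the toy solvent reproduces any particular real solvation
environment.

# Hybrid charge intermediates

`derive_average_charges()` evaluates the instantaneous high-level charges on
a deterministic, evenly spaced selection of configurations across replicates
(200 by default: 25 from each of 8 replicates), averages per atom, records
the per-atom standard deviation (n−1 denominator) and re-neutralizes the
mean.  The provenance of the pool names the variant: a gas-phase pool gives
`MULL(gas)` (in this toy exactly the base charges, since an isolated solute
feels no potential), a solvated low-level pool `MULL(solv)`, a solvated
high-level pool `MULL(solv*)`.

`make_intermediate_system()` grafts such a fixed charge set onto the low
level, producing the MULL intermediate state; switching then runs
MULL→high, and the cheap low-level leg MM↔MULL is computed by
`delta_a_charge_leg()`: equilibrium sampling at charge-interpolated states
$q_i(\lambda) = (1-\lambda)q_i^{MM} + \lambda q_i^{MULL}$ (default ladder
$\lambda = 0, 0.25, 0.5, 0.75, 1$) with pairwise BAR.  Because the
electrostatic energy is linear in the charges, the hybrid energy of the
charge-perturbation system is *identical* to the energy of the interpolated
charge set, so one machinery serves both purposes.

Averaging at the MULL intermediate itself is only approximately idempotent:
the solvent relaxes slightly further under the enhanced charges, so one more
derive-average iteration drifts by a small fraction of the MM-to-target
charge difference.  The test suite bounds this drift rather than asserting
exact fixed-point behavior.

# Analyses

* Charge-distribution metrics against a reference set (conventionally
  `MULL(solv*)`): `rmsd_q()`, the differential dipole
  $\Delta\vec\mu = \sum_i \Delta q_i\,\vec r_i$ (reported in Debye,
  1 e·Å = 4.80320 D; origin-independent when the net charge difference is
  zero -- all shipped fixtures are neutral), and the angle between the two
  full dipole vectors.  Dipoles are evaluated on the rigid reference
  geometry.
* First solvation shell: a solvent site counts if it lies within the cutoff
  (default 3.0 Å, *inclusive*) of any heavy solute atom;
  `delta_n_waters()` compares mean occupancies between two trajectories.
* Stokes-shift relaxation: trajectories restarted at the high level from
  configurations equilibrated at a lower state record the gap
  $\Delta U(t) = U_{\mathrm{high}}(t) - U_{\mathrm{start}}(t)$;
  `stokes_relaxation()` averages them, estimates the $t\to\infty$ baseline
  over a window (default: the final 20% of the series, which reproduces a
  2000-entry average for a 10 ps series sampled at 1 fs) and subtracts it.
  `fit_mono_exponential()` fits $\Delta U_0\,e^{-t/\tau}$ to the shifted
  series with the first 0.5 ps discarded, so the fitted $\tau$ tracks the
  *slow* reorientation process.  No additive offset is fitted -- the
  baseline is already subtracted.  Initial guesses come from a log-linear
  regression with a small grid of fallback time constants; the optimizer is
  a Levenberg--Marquardt nonlinear least squares.
* Reporting: `delta_delta_a()` forms the deviation from a reference
  (optionally including the staged low-level leg), `mad_and_spread()`
  summarizes a set of deviations by the mean absolute value and the
  smallest/largest absolute deviation (deviations are measured from zero,
  not from the sample mean).

# Reproducibility and numerical choices

All stochastic components draw from a dedicated xoshiro256++ generator in
the compiled engine, seeded deterministically from one master seed through
`child_seed(seed, tag, index)` -- a splittable integer scheme that keeps
replicates, switches, relaxation trajectories and bootstrap resamples
statistically independent yet bit-reproducible, independent of R's global
RNG state.  Identical seeds give bit-identical pools and work tables.

The integrator is BAOAB Langevin splitting (translational for the harmonic
particle, rotational on the unit sphere for the rotors, with the
orientation constraint enforced by projection).  Energies are deterministic
functions of the configuration; equal configurations give bit-identical
energies.

Problem sizes used by the shipped validation workloads (the test suite and
`scripts/acceptance.R`) were chosen as the smallest ensembles at which each
stochastic assertion has comfortable statistical power: equilibrium pools of
8 replicates × 125 saved configurations for the dipole bath, 200-switch
ensembles of 2000 steps (with 5000-step two-sided switches as the
reference), 11-window staged BAR for the harmonic oracle, eight ensembles of
500 + 500 switches for the Crooks-slope calibration, and 100-trajectory ×
6 ps relaxation ensembles for the Stokes fits.

# Known limitations

* The toy solvent has no rotor–rotor coupling, frozen geometry and no
  long-range treatment; see above for what this excludes.
* `MULL(gas)` degenerates to the MM charges in the toy (no vacuum
  polarization), so gas-derived intermediates cannot be distinguished from
  the MM route here.
* The work fluctuation theorems hold for the discrete integrator only up to
  $O((\omega\,\delta t)^2)$; calibration checks must use timesteps small
  relative to the stiffest mode, as the shipped tests do.
* One-sided (JAR) estimates on strongly dissipative routes (large
  $\sigma_W$) carry the usual exponential-average bias; the package reports
  $\sigma_W$ precisely so users treat such estimates with suspicion.
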