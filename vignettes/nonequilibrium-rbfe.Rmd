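---
title: "Work-based free energy estimation and its diagnostics"
author: "neqfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Work-based free energy estimation and its diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqfe)
```

## The model

Relative binding free energies are computed around a thermodynamic cycle:
an alchemical transformation of ligand L1 into L2 is carried out in the
bound state (complex leg) and in bulk solvent (solvent leg), and
`ddG = dG_complex - dG_solvent`. Each leg's `dG` comes either from
equilibrium sampling at intermediate states of the coupling parameter
`lambda` (thermodynamic integration), or from the work recorded during
fast, irreversible switching transitions between the two end states, run
in both directions.

The nonequilibrium estimators all rest on the Crooks fluctuation theorem,

$$\frac{P_f(W)}{P_r(-W)} = e^{\beta (W - \Delta G)},$$

where `P_f` is the density of forward work, `P_r` that of reverse work in
its as-measured sign, and `beta = 1/kT` (we use
`kB = 0.0019872041 kcal/(mol K)` and default `T = 300 K`, so
`kT = 0.59616 kcal/mol`). Three consequences are implemented:

* **Jarzynski**: $\Delta G = -kT \ln \langle e^{-\beta W} \rangle$ over
  one direction, computed as a log-sum-exp for stability. The exponential
  average is tail-dominated, so the one-sided estimate is biased at finite
  `n`; for Gaussian work of width `sigma` the population value is
  $\mu - \beta\sigma^2/2$, which is the closed form our tests check
  against.
* **Crooks Gaussian intersection (CGI)**: normal fits to the forward and
  negated-reverse works cross at `W = dG`. Equal fitted variances give the
  midpoint of the means; unequal variances give a quadratic whose root
  *between the two means* is the physical intersection.
* **BAR**: the Bennett self-consistent equation with the logistic function
  `f(x) = 1/(1 + e^x)`,
  $\sum_f f(\beta(W_f - \Delta G) + M) = \sum_r f(\beta(W_r + \Delta G) - M)$,
  `M = ln(n_f/n_r)`. The left side is strictly decreasing and the right
  strictly increasing in `dG`, so the root is unique and a bracketed
  derivative-free search is both robust and deterministic.

The equilibrium arm integrates per-window ensemble means of `dH/dlambda`
with the composite trapezoid rule over the window grid (default: 13 evenly
spaced windows, `lambda = i/12`). The trapezoid is exact for profiles up
to first degree; on the quadratic fixture `3 lambda^2` the 13-window value
is `1 + 6/1728 = 1.003472`, which the tests assert bit-for-bit — the
discretization error is part of the protocol, not noise.

## Assumptions and conventions

* Reverse works are stored **as measured** on the 1 → 0 path; estimators
  negate internally. Files therefore contain physical quantities.
* Energies are kcal/mol everywhere inside the package; kJ/mol input is
  converted at the I/O boundary (factor 4.184) and never inside an
  estimator.
* Transitions that end before reaching the final lambda state carry
  `completed = FALSE`; they are excluded from every estimator and tallied
  by `failure_accounting()`. Low work-distribution overlap (below 1%)
  raises a warning (code `W001`) but never a rejection: a poor estimate
  with a flag is more useful than a hole in a large-scale campaign.
* Uncertainties are bootstrap standard errors (resampling work values with
  replacement, independently per direction; default 1000 resamples) for
  every estimator, so uncertainties are comparable across estimators. The
  BAR analytic variance is deliberately not the primary uncertainty.

## What the synthetic generators emulate

`generate_crooks_gaussian()` draws forward work from
`N(dG + beta sigma^2/2, sigma)` and negated-reverse work from
`N(dG - beta sigma^2/2, sigma)`: the unique Gaussian pair satisfying the
fluctuation theorem exactly, with `beta sigma^2/2` the mean dissipated
work. Equal sigmas are required because unequal Gaussian widths cannot
close the theorem.

`generate_crooks_mixture()` produces the skewed, asymmetric, fat-tailed or
multimodal work distributions seen in switching simulations of flexible
ligands. The forward density is a Gaussian mixture; multiplying it by
`exp(-beta(W - dG))` maps each component analytically onto a reweighted,
shifted Gaussian, so the reverse density is sampled *exactly* — no
rejection step, no approximate closure. One subtlety: an arbitrary
mixture does not satisfy the Jarzynski normalization
$\langle e^{-\beta W}\rangle_f = e^{-\beta \Delta G}$ at the requested
`dG`, so the forward mixture is rigidly shifted until it does. The
`offset` entries of `mixture_params` therefore control shape only; the
true free energy of every generated set is exactly `true_dg`, which is
what makes the generator usable as an estimator test bed.

Generated samples carry emulated provenance — replica assignment
(round-robin over 5 replicas by default) and evenly spaced snapshot times
over a 10 ns equilibrium run — and an optional independent failure flag
per sample. The helper `dissipation_sigma()` models the narrowing of work
distributions with slower switching as
`sigma(tau) = sigma_ref (tau_ref/tau)^(1/2)`; the square-root default is
the linear-response behaviour, and the exponent is exposed because real
systems need not follow it.

What the generators do **not** emulate: time correlation between
transitions started from the same replica, lambda-dependent friction,
conformational trapping that makes forward and reverse ensembles sample
different basins, or any system-specific physics. Passing tests on
synthetic data therefore demonstrate the correctness of the estimators
and diagnostics, not the adequacy of any simulation protocol for a real
target.

The benchmark generator draws per-pair overlaps (6% point mass at exactly
zero, uniform otherwise), true `ddG` uniform on ±3 kcal/mol (the typical
span of congeneric-series affinities), experimental noise of
0.4 kcal/mol (a typical experimental uncertainty), and prediction error
with standard deviation `2.5 (1 - overlap) + 0.3` kcal/mol. The decreasing
noise function is a modelling choice — the empirical relation between
accuracy and overlap is known only to be inverse — and is exposed as a
parameter.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| temperature | 300 | K | standard simulation temperature |
| lambda windows (TI) | 13 | – | standard ensemble-TI grid |
| replicas per window / end point | 5 | – | minimum reliable ensemble size |
| equilibrium run per replica | 10 | ns | end-state sampling recommendation |
| transitions per direction | 100 | – | convergence sets in beyond this |
| transition length | 250 | ps | shorter runs fail more and spread more |
| per-lambda duration floor | 2 | ps | stability threshold (warning `W002`) |
| BAR tolerance | 1e-8 | kcal/mol | far below any physical resolution |
| bootstrap resamples (per estimate) | 1000 | – | SE of the SE ≈ 2% |
| replica-increment resamples | 100000 | – | percentile CIs need the tail mass |

`recommend_protocol()` turns the protocol rows of this table into advisory
findings (warning `W003`), never errors.

## Numerical choices

* **Overlap density estimate**: shared-grid histograms over the union of
  both sample ranges with Freedman–Diaconis width on the pooled sample.
  Histograms (rather than kernel estimates) make the two exact limits
  exact: identical samples give overlap 1 by integer-count arithmetic,
  disjoint supports give 0.
* **CGI tie-breaks**: fitted standard deviations within a relative 1e-6
  are treated as equal (midpoint); a degenerate (zero-variance) direction
  or a quadratic with no root between the means falls back to the midpoint
  with `converged = FALSE`.
* **BAR bracketing**: the bracket grows outward from the CGI midpoint and
  is capped at `max|W| + 50 kT`; a root that cannot be bracketed there is
  reported as the midpoint with `converged = FALSE` plus a warning.
* **Transition subsampling** (`transition_count_convergence`): "uniformly
  selected" is implemented as a deterministic stride — every
  `floor(total/N)`-th completed transition — so that convergence curves
  are reproducible without a seed; seeded random subsampling is available
  behind `random = TRUE`.
* **Overlap bins**: the accuracy-vs-overlap bins are `{0}`, `(0, 0.5]`
  and `(0.5, 1]`; an overlap of exactly 0.5 belongs to the middle bin.
* **Snapshot schedules**: "evenly extracted" is read as equal spacing
  within each replica with the final extraction at the end of the run
  (maximizing equilibration before the first snapshot), remainders
  assigned round-robin, times snapped to the saved-frame grid.
* **Seeding**: every stochastic function takes an explicit seed and
  restores the caller's RNG state; identical spec + seed gives
  byte-identical output. The replica-increment bootstrap draws indices,
  not values, which makes the curve exactly scale-equivariant at a fixed
  seed (exact to the last bit for power-of-two scale factors, where
  floating-point multiplication commutes with the arithmetic).

## Problem sizes used by the test suite

The packaged checks run on a single CPU: the estimator-recovery sweep uses
nine (dG, sigma) combinations × 100 seeds at 5000 transitions per
direction with 100-resample bootstrap SEs (the per-estimate default of
1000 resamples is unnecessary when only the 3-SE coverage indicator is
consumed); Jarzynski is checked at 10^6 samples against its closed form
with a jackknife SE; overlap and fluctuation-slope checks use 10^5
samples; the replica-increment bootstrap runs its full 10^5 resamples.
These sizes are stated here so that anyone rescaling them knows what the
reference run was.

## Known limitations

* Per-window standard errors in TI are propagated as independent; no
  autocorrelation or effective-sample-size correction is applied (the
  ensemble spread across replicas is the recommended uncertainty for
  production data).
* No multistate estimator (MBAR) and no weighted-histogram methods; the
  package covers the two-state work estimators plus TI.
* Multimodality is diagnosed through skewness, kurtosis and the
  normal-probability-plot correlation, not a formal dip test.
* The CLI writes delimited text only; trajectory or MD-engine log parsing
  is out of scope by design.
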