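---
title: "An age-structured compartment model of replicative senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An age-structured compartment model of replicative senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senodyn)
```

## The model

A primary cell culture passaged continuously drifts from exponential growth
into a predominantly senescent state. `senodyn` describes this transition
with a deterministic compartment model. Live cells are **proliferative**
(`P`), **growth-arrested** (`G`), **apoptotic** (`A`) or **senescent** (`S`);
apoptotic cells drain irreversibly into a **dead** pool (`D`) that detaches
from the culture and is invisible to every readout. Proliferative cells are
stratified by *doubling age*: `P_i` holds cells that have divided `i` times,
for `i = 0, ..., N-1`, with `N` a Hayflick-like division limit (default 50).

Transitions are first-order with per-hour rates:

* **Division** moves cells out of `P_i` at rate `div[i]` and deposits the two
  daughters in `P_{i+1}` — the influx is twice the leaving flux, which is
  the only source of new cells in the model. Division out of the oldest
  class `P_{N-1}` lands in `S` (senescence by replicative exhaustion), with
  the same factor 2.
* **Jumps** into `S`, `G` and `A` carry cells one-for-one out of any `P_i`
  at rates `sen[i]`, `arr[i]`, `apo[i]` (DNA damage and stress-driven exits
  that do not require division).
* Growth-arrested cells convert to senescent at the scalar rate `m_GS`;
  apoptotic cells die at `m_AD`.

Each of the four age-dependent rates is constrained to be a **linear ladder**
in doubling age, parameterized by its endpoints at `P_0` and `P_{N-1}`
(`linear_rate_ladder()`). Division rates decrease with age (cell-cycle
slowdown); the senescence, arrest and apoptosis rates may rise with age
(accumulating damage, paracrine signalling from senescent neighbours). This
reduces 4 × N rate constants to 8 free endpoint parameters.

The state derivative (in `derivative()`, and compiled in C for the solver)
is, writing `exit[i] = div[i] + sen[i] + arr[i] + apo[i]`:

```
dP_0/dt = -exit[0] P_0
dP_i/dt = 2 div[i-1] P_{i-1} - exit[i] P_i          (1 <= i <= N-1)
dG/dt   = sum_i arr[i] P_i - m_GS G
dA/dt   = sum_i apo[i] P_i - m_AD A
dS/dt   = 2 div[N-1] P_{N-1} + sum_i sen[i] P_i + m_GS G
dD/dt   = m_AD A
```

Senescence is absorbing: nothing leaves `S`, so `S(t)` is non-decreasing.
The live total is `TP = sum(P) + G + A + S` (dead cells excluded — this is
what `m_AD` makes observable), and population doublings are
`PD(t) = log2(TP(t)/TP(0))`. The default initial condition is a
dimensionless culture of size 1 seeded entirely in `P_0`; absolute cell
counts never enter the marker comparison, only proportions and doublings.

Reversal of growth arrest (G back to P) and G-to-A transitions are
deliberately absent, as are cell-cycle phases, spatial interactions and
single-cell stochasticity: the model is a population-level mean-field
description.

## Marker mapping

Experiments observe stained fractions, not compartments. The five readouts
(`marker_readouts()`) are percentages of `TP` except PD:

* `SA-b-Gal = 100 S / TP` and `TUNEL = 100 A / TP` map one-to-one.
* `Ki-67 = 100 (sum(P) + f_GK G) / TP`: all proliferative cells plus a
  fitted fraction `f_GK` of growth-arrested cells retain the antigen.
* `gH2AX = 100 (S + A + f_P sum(P) + f_GH G) / TP`: DNA damage marks all
  senescent and apoptotic cells plus fitted fractions of `P` and `G`.

The three fractions (`marker_params()`) lie in [0, 1] and are fitted, not
fixed, because direct evidence for them is thin. Together with the 8 ladder
endpoints and `m_GS`, `m_AD` this gives **13 tunable parameters**; `N` is a
structural constant whose choice the fit is insensitive to (tested at
N = 40/50/60). The packaged reference file
(`reference_parameters()`) carries an optimized set in which, for example,
the seed-state gH2AX readout is exactly 100 × `f_P` = 23.85% and Ki-67 is
100%.

## Fitting

`model_cost()` is a range-normalized mean squared error: per marker,
residuals (model − record, replicates entering individually) are divided by
the marker's observed range, squared, averaged, weighted (default 1) and
summed. Range normalization puts doublings (span ~17–20) and percentages
(span ~100) on the same footing and makes "percent increase in error"
statistics scale-free.

Observed PD is cumulative from the culture's history (a passage-5 seed
reports PD 5), while model PD starts at 0. The default `subtract-first`
alignment re-centres *both* sides at the earliest observed PD time, which
makes the alignment — and hence the cost — invariant to dropping early
records; this matters for the holdout and sparse-design analyses, which do
exactly that. A free additive offset and a raw mode are available.

`fit_ga()` is a real-coded genetic algorithm over a 13-dimensional box:
rates are searched log-uniformly in [1e-5, 1e-1] /h (the optimized values
span ~7e-4 to 2.6e-2, and log scale equalizes sensitivity), fractions
uniformly in [0, 1]. Defaults: population 200, 300 generations, tournament
selection (size 3), uniform crossover (p = 0.7), per-gene Gaussian mutation
(sd = 10% of box width, p = 0.15), elitism 2. These are conventional GA
settings; the fitted optimum is insensitive to them because
`refine_gradient()` — box-constrained L-BFGS-B over central-difference
gradients — polishes the GA's best individual and reports the terminal
gradient norm as the local-minimum check. The test suite and examples use
much smaller GA budgets (populations 16–120, tens of generations): the cost
surface at desk scale is smooth enough that refinement does most of the
work, and a full cold fit of 80 noiseless records completes in under a
minute. Cold starts at the default budget remain available for fidelity.

On noise-free synthetic data the pipeline recovers the generating model to
a cost below 1e-4 of the marker variance and overlays the true marker
trajectories to within 0.5 percentage points; a flat-ladder truth is
recovered with relative endpoint differences below 5%.

## Synthetic data

`generate_dataset()` emulates the motivating experimental design: 16
passage samplings at 160 h intervals over 0–2400 h (passages labelled
5–20), all five markers, triplicate measurements, additive Gaussian noise
truncated to the physical ranges, and PD emitted with a +5 cumulative
offset so the alignment machinery is exercised. Noise defaults are sd = 3
percentage points for stains and 0.2 doublings for PD — plausible
microscopy-count variability (the assays count a few hundred cells per
replicate), chosen once and configurable. Truncation bias is negligible
(<0.15 pp) for values more than ~10 pp from the rails.

What the generator does **not** emulate: freeze–thaw or seeding-density
perturbations, passage-to-passage resets, non-Gaussian staining artefacts,
or replicate correlation. Passing recovery tests on this generator
therefore demonstrates the estimator's self-consistency, not robustness to
real-world assay pathology.

## Downstream analyses

* `apply_strategy()` / `design_strategy_error()` quantify sparse sampling
  plans. The reduced-data refit is scored on the **full** dataset, so the
  percent increase over the full-data baseline measures information lost by
  not sampling; scoring on the reduced data would reward discarding
  awkward points. `skip` with stride `s` retains the first passage and
  every `(s+1)`-th thereafter (stride 2 keeps 6 of 16 passages, 30 of 80
  per-passage measurements). Refits warm-start from the full-data optimum
  to keep runtimes at desk scale (a cold-start flag exists); at `k = 0` the
  optimization problem is unchanged and the error is 0 by construction. On
  noisy synthetic data, dropping the last 6 passages costs markedly more
  than skip-2 despite removing fewer points — late passages, where the
  trajectories plateau, are the most informative.
* `sensitivity_grid()` / `sensitivity_scan()` map percent cost increases
  over ladder-endpoint pairs (the grid diagonal is an age-independent
  ladder) or over the scalar rates and marker fractions. Simulation
  failures at extreme rates become `NA` cells rather than errors.
* `holdout_analysis()` removes a random fraction of records, refits, and
  scores on the full data. On noiseless data the relative-increase ratio is
  ill-posed (numerator and denominator are both optimizer noise), so the
  meaningful statements are: absolute refit cost stays at the noise floor
  on noiseless data, and the relative increase is small (a few percent) on
  noisy data.
* `peak_growth_arrest_time()` locates the maximum of `G/TP` by discrete
  argmax plus quadratic interpolation; a monotone fraction raises a classed
  `senodyn_no_peak` condition. The interior peak exists because `G` drains
  into `S`: with `m_GS = 0` the growth-arrested fraction saturates instead
  of peaking.
* `time_to_senescence_fraction()` reports the first crossing of
  `S/TP >= threshold` on a dense 1 h grid with linear interpolation in the
  bracketing step, or a classed `senodyn_not_reached` condition carrying
  the final fraction. Under the reference parameters this clock responds
  far more strongly to the division ladder than to the apoptosis ladder.

## Numerical choices

* Integration: `deSolve::lsoda` over a compiled C right-hand side,
  rtol = 1e-8, atol = 1e-10. The system is linear and non-stiff at the
  reference magnitudes; an independent fixed-step RK4 oracle over the
  R-level derivative (step 0.5 h, global error ~1e-9 for these rates)
  agrees to better than 1e-5, and halving tolerances moves no component by
  more than 1e-6 — both measured relative to the component with a floor of
  1e-6 × TP, because the proliferative pool underflows any absolute solver
  tolerance once the culture is essentially senescent.
* The GA is seeded from R's RNG; every stochastic entry point
  (`fit_ga()`, `generate_dataset()`, `holdout_analysis()`) takes an
  explicit integer seed and is reproducible bit-for-bit.
* Ladder interpolation is over `i/(N-1)` so the two fitted endpoints are
  the rates of the youngest and oldest proliferative classes exactly.
* Degenerate inputs: `N = 1` collapses to a two-compartment model (used as
  a closed-form test case); zero observed range in a marker falls back to
  an unnormalized residual; ties in the peak parabola fall back to the grid
  argmax.

## Known limitations

* Peak timing of the growth-arrested *fraction* is sensitive to the last
  printed digit of the optimized rates and to the exact transition
  conventions; the absolute `G` count peaks later than the fraction. The
  packaged reference set places the fraction peak near 1.8 × 10³ h (the
  acceptance script recomputes this).
* The model cannot represent interrupted cultures (freeze–thaw, reseeding
  at fixed density), reversal of arrest, or cell-cycle-stage-specific
  staining; fits to data from such protocols will absorb those effects
  into biased rates.
* Parameter identifiability at a single noise realization is good but not
  perfect; ladder endpoint pairs trade off weakly against the scalar rates.
  The holdout and sensitivity tools quantify this for a given dataset.
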