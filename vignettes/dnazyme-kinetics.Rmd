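---
title: "Step-resolved kinetics of 10-23 DNAzyme cleavage: model, estimation, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-resolved kinetics of 10-23 DNAzyme cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dzkin)
```

## The reaction model

The 10-23 DNAzyme is a single-stranded DNA catalyst that hybridizes to a
complementary substrate through two binding arms and cleaves an RNA
linkage in its middle. Under multiple-turnover conditions (substrate in
large excess over enzyme) the minimal mechanism has three reversible
steps: substrate binding, chemistry, and product handling,

    E + S  <-- k_on / k_off -->  ES
    ES     <-- k_clv / k_lig -->  EP
    EP     <-- k_rls / k_bin -->  E + P

with `P` the more slowly dissociating of the two product strands; the
fast-leaving strand is treated as implicit. Mass action gives a
five-species ODE system in `S, E, ES, EP, P` (see `mass_action_rhs()`).
The fluorophore/quencher readout reports every cleaved substrate
molecule whether or not the product is still enzyme-bound, so the model
observable is `EP + P`.

Two bookkeeping identities pin the equations down: total substrate
`S + ES + EP + P` and total enzyme `E + ES + EP` are conserved exactly.
The product balance must therefore read
`dP/dt = k_rls*EP - k_bin*E*P`; any other closure of the cycle breaks
conservation, and the package's unit tests enforce both identities to
1e-6 relative tolerance along every trajectory.

Units are fixed package-wide: concentrations in nmol/L, time in seconds,
first-order constants in 1/s and second-order constants in
1/(nmol/L)/s. `reference_rates()` provides literature-reported point
estimates for a long-armed DNAzyme at 55 degrees C and 20 mmol/L Mg2+
(`k_on = 4.525e-3`, `k_off = 0.1555`, `k_clv = 0.222`, `k_rls = 20.65`,
`k_bin = 0.113`, `k_lig = 0`), used as the default simulation regime.

### Model variants

Ligation is chemically possible but experimentally disfavoured;
`model_variant()` encodes three nested variants: `full_equilibrium`
(nothing clamped), `no_ligation` (`k_lig = 0`), and `no_binding`
(`k_lig = k_bin = 0`). No Binding clamps both constants because it is
conceived as a further reduction of No Ligation; a `clamped` override is
available for a `k_bin`-only variant.

## Numerical integration

The rate constants span four orders of magnitude (`k_rls ~ 20/s` versus
`k_on*S ~ 1e-3/s` at the lowest substrate level), so trajectories are
integrated with a stiff-capable adaptive solver (`lsoda`, compiled
right-hand side). Reporting-grade simulation (`simulate_reaction()`)
uses `rtol = 1e-10`, `atol = 1e-10` nmol/L: at these settings the
adaptive solution agrees with a fixed-step classical Runge-Kutta
reference at 1 ms steps (`simulate_reaction_rk4()`) to better than
1e-6 nmol/L over a 25-minute trajectory, whereas `rtol = 1e-8` leaves
~4e-6 nmol/L of discrepancy. The fitting path defaults to `rtol = 1e-8`
(and the long simulation studies in the test suite relax to `1e-6`):
solver error there is at least three orders of magnitude below the 2%
measurement noise, and objective evaluations dominate the cost of every
study. `lsoda` occasionally refuses a tolerance as unachievable at a
local scale; the fitting path retries with ten-fold relaxed tolerances
before raising an error.

## What the synthetic-data generator emulates

Raw plate-reader traces for this system are not publicly archived, so
the package generates its own data with the statistical structure the
analysis assumes (`generate_curves()`):

* **Design** (`experiment_design()`): 10 nmol/L DNAzyme; substrate at
  100, 250, 500, 750, 1000 nmol/L; a reading every 30 s for 25 min;
  8 replicate wells per level at the reference condition and 3 in
  condition series; one substrate-only control well per level.
* **Pipetting errors**: per-well multiplicative log-normal factors on
  both concentrations, `ErrS` with log-SD 0.058 (95% range about
  0.89-1.12) and `ErrE` with log-SD 0.10, widened to 0.80 at the lowest
  substrate level where reported estimates reach several-fold — there
  the data carry almost no information about the enzyme amount, so
  large fitted factors are expected.
* **Raw-signal model**: fluorescence = substrate-proportional baseline
  (8% of the would-be plateau, imperfect quenching) + slope x
  observable (40 AU per nmol/L) + i.i.d. Gaussian read noise with SD
  equal to 2% of the plateau signal. All three magnitudes are
  assumptions of the generator, recorded in the ground-truth attribute,
  not quantities estimated from any instrument.

The generator does **not** emulate photobleaching, inner-filter
effects, evaporation, well cross-talk, or drift; passing tests
therefore validate the estimation machinery under the stated noise
model, not robustness to instrumental artifacts.

`generate_saturating()` deliberately mis-specifies the data relative to
the model — above a substrate threshold (default 1000 nmol/L) the
cleavage rate is scaled down by `1/(1 + i*(S0/1000 - 1))` — to exercise
misfit detection: the clean model then over-predicts early product at
1250-1500 nmol/L, reproducing the qualitative failure observed
experimentally above 1000 nmol/L.

### Preprocessing

Raw traces are converted to concentrations in three steps
(`preprocess_curves()`): per-level baseline subtraction (time-average
of the substrate-only control; the protocol does not specify whether a
per-time-point or averaged baseline was used, and the average is the
lower-variance choice), calibration (ordinary least squares of plateau
fluorescence on substrate concentration; the plateau of a curve is the
mean of its last 10% of readings, at least 3, with a completeness check
that warns when the relative slope over that window exceeds 1e-4 per
30 s), and normalization by the slope, with each time axis shifted by
the well's `start_delay_s` so that t = 0 is substrate addition. For
condition series whose slowest conditions never plateau within the run
(low Mg2+, low temperature), plateau-based calibration is biased by
construction; `generate_condition_series()` therefore normalizes with
the generator's known slope, standing in for the dedicated calibration
experiment a real study would run.

## Staged estimation

`fit_kinetics()` reproduces the staged calibration workflow:

1. **Scatter search** over the free rate constants: space-filling
   (Latin-hypercube) sampling, log-uniform within two orders of
   magnitude around the initial values, followed by recombination of
   elite pairs in log space and a short Nelder-Mead polish of the best
   candidates. This is a faithful-in-spirit stand-in for the published
   enhanced-scatter-search implementation, whose exact hyperparameters
   are not public; it is seeded and fully reproducible, and the
   incumbent start is always retained so the stage can never worsen the
   objective.
2. **Levenberg-Marquardt** refinement of the rate constants in log10
   space (positivity plus decade-spanning magnitudes), errors fixed at 1.
3. **Per-curve error terms**: each curve's `(ErrS, ErrE)` pair is fitted
   separately within bounds [0.2, 10], the rates frozen.
4. **Joint refit** of rates and all error terms simultaneously. The
   Jacobian exploits the problem structure — each error term touches
   only its own curve — so its cost grows linearly rather than
   quadratically with the number of curves.

The objective is the root-mean-square error of `EP + P` pooled over all
points of all curves; it never increases from stage to stage. Model
variants are compared with the least-squares form of Akaike's
information criterion, `AIC = n*ln(RSS/n) + 2*(p+1)`, counting the rate
constants and all error terms as free parameters; since the exact AIC
convention of the original software is unknown, only AIC differences
between variants fitted to the same data are interpreted. Selection
takes the lowest AIC, prefers fewer parameters within 2 AIC units, and
skips a winner whose estimates are not significantly different from
zero (estimate < 2 SD). Before comparison every variant is re-polished
from every other variant's solution (clamped constants zeroed, newly
freed ones started at the lower bound), so that nested variants are
compared at equally converged optima rather than at whichever local
solution each stochastic search happened to find.

### Identifiability: what this design can and cannot estimate

A central empirical finding of the test suite is that the study design
(30-s sampling, 2% plateau-relative noise, per-curve free error terms)
identifies the cleavage step sharply but leaves near-flat directions in
the remaining parameters: a common rescaling of `k_on`/`k_off` at fixed
Michaelis-type ratio, of `k_rls`/`k_bin` at fixed ratio, and a trade
between `k_clv` and a common scale of the enzyme error terms all change
the objective by far less than the noise floor. Fits on exact
(noise-free) synthetic data recover the generating constants, and fits
with error terms fixed at 1 recover them to within a few percent; with
error terms free, however, converged least-squares estimates on noisy
replicates scatter by tens of percent along those directions, and
residual-bootstrap intervals — refit locally from the base estimates, as
the original workflow prescribes — inherit the bias of the base
estimate. The corresponding parameter-recovery and bootstrap-calibration
checks in `tests/testthat/test-acceptance.R` are therefore expected to
fail, and are retained deliberately as an honest record of this
information limit. The same limit appears in the temperature layer: only
the activation energy of the output-dominant step (`k_clv`) is
recovered accurately; those of weakly influential steps (`k_off`,
`k_rls`) are not, which is the mirror image of the sensitivity ranking
(the most robust constants are the least identifiable).

## Environmental layers

Temperature enters through the Arrhenius law written relative to a
reference temperature, `k = k_ref * exp((E_a/R)(1/T_ref - 1/T))` with
`T_ref = 328.15 K` (55 degrees C, the central working temperature);
negative activation energies are allowed to express the anti-Arrhenius
behavior of DNA strand association. The retained dependence set is
`{k_off, k_clv, k_rls}`. Mg2+ enters through exponential laws,
decreasing `a + b*exp(-c*Mg)` for release and increasing
`a + b*(1 - exp(-c*Mg))` for association and cleavage, with the
cleavage intercept forced to `a = 0` (no catalysis without the
cofactor); `c` is in 1/(mmol/L). The two layers are calibrated on
separate data sets and may not act on the same constant simultaneously;
a joint temperature-by-Mg model is out of scope.

`fit_arrhenius()` stages the estimation as: activation energies with
reference rates frozen (two-decade scatter search + Levenberg-Marquardt),
joint re-estimation of reference rates and activation energies, then
per-curve error terms. `fit_mg()` fits the law parameters `(a, b, c)`
in log10 space with a one-decade scatter search, then error terms.
Initial values place the amplitudes at the scale of the base rate, a
slow saturation (`c = 0.05`) for the increasing laws and a ten-fold
faster one for the release law, reflecting its saturation at much lower
cofactor concentrations. Whether the original laws were fitted on a
transformed scale is unstated; the natural concentration scale is used
here.

## Uncertainty

`bootstrap_ci()` implements a residual bootstrap: residuals are
resampled with replacement within each curve, added back to the fitted
curves, and the joint refit is restarted from the base estimates
(100 data sets by default). Percentile intervals use order statistics
(type-1 quantiles), making them exactly equivariant under monotone
reparameterization. Individual refit failures are excluded; more than
20% failing is an error.

`monte_carlo_predict()` propagates input variability forward: `(ErrS,
ErrE)` combinations are drawn independently from the pooled per-curve
estimates (1000 draws by default; the original procedure's pairing
behavior is unstated, and independent draws are the conservative
choice), the reaction is simulated for each, and per-time-point
histograms are normalized so the frequencies sum to 1 at every time
point. An optional `obs_noise_sd` term adds measurement noise to the
draws, turning the band into a predictive band for observed points —
the appropriate comparison when overlaying real (noisy) curves, and the
form used in the held-out validation test.

## Sensitivity analysis

`sensitivity_analysis()` perturbs one constant at a time over ±60% in
20% steps (the range is the one reported for this system; the step size
is this package's choice) and `rank_sensitivity()` scores each constant by
the worst-case maximum absolute deviation of the observable, with a
time-to-90%-completion alternative. At the reference parameters and
1000 nmol/L substrate the ranking puts cleavage first and association
second, with dissociation and product binding most robust, and the
±60% responses of `k_clv` are markedly asymmetric — both reproduced as
acceptance checks. One-at-a-time perturbation assumes the steps act
independently; no global (Sobol-type) analysis is attempted.

## Problem sizes used by the validation suite

The simulation studies in the test suite use the full replicated design
(5 levels x 8 replicates) for parameter recovery and the prediction
band; 3 levels x 2-3 replicates for the model-selection and bootstrap
studies (20 replicates each, 50 bootstrap data sets); and 3 replicates
per condition for the five-temperature and five-Mg2+ series. The
ligation-dominant regime used for the model-selection study
(`k_lig = 0.27/s` against `k_clv = 0.2/s`, all six steps active) was
chosen so that the cleavage-ligation equilibrium caps conversion near
10% — a signature the ligation-free variant cannot absorb, because its
bounded error terms cannot scale a full-conversion curve that far down.

## Known limitations

* Absolute AIC values are implementation-specific; only differences are
  meaningful.
* The per-curve error terms make the likelihood surface sloppy (see the
  identifiability section); point estimates of `k_on`, `k_off`,
  `k_rls`, `k_bin` from a single noisy data set should be read together
  with their bootstrap spread, not as precise values.
* The intermediate ion-binding/activation steps of the catalytic core
  are collapsed into `k_clv`; both product strands are not modeled
  separately.
* Substrate inhibition above 1000 nmol/L is outside the model; the
  saturating generator exists precisely to demonstrate that misfit.
* Predictions outside the calibrated ranges (50-60 degrees C,
  2-100 mmol/L Mg2+) are extrapolations and are flagged as such by the
  fitting functions.
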