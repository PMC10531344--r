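# dzkin — step-resolved kinetics of 10-23 DNAzyme cleavage

RNA-cleaving 10-23 DNAzymes are single-stranded DNA catalysts used in
biosensing and nucleic-acid therapeutics. Their overall cleavage rate is
usually summarized by a single observed constant, which hides *why* a
given design is fast or slow. `dzkin` is for researchers who measure
fluorescent cleavage progress curves on a plate reader and want the
individual reaction steps back: association/dissociation of the
DNAzyme–substrate complex, cleavage (and optionally ligation), and
release/re-binding of the slow product strand.

The model is the mass-action ODE system of the minimal mechanism

    E + S  ⇌(k_on, k_off)  ES  ⇌(k_clv, k_lig)  EP  ⇌(k_rls, k_bin)  E + P

in five species (S, E, ES, EP, P; nmol/L, seconds), with the assay
observable EP + P. On top of it the package provides:

* stiff adaptive simulation with a compiled right-hand side, plus a
  fixed-step Runge–Kutta reference integrator;
* plate-reader preprocessing (substrate-only baseline subtraction,
  plateau calibration, slope normalization, dead-time shift);
* the staged calibration workflow — log-space scatter search,
  Levenberg–Marquardt, per-curve concentration-error terms
  (`S(0) = ErrS·S̄₀`, `E(0) = ErrE·Ē₀`), joint refit — with AIC
  comparison of nested model variants (full equilibrium / no ligation /
  no binding);
* Arrhenius temperature and exponential Mg²⁺ layers on the rate
  constants, each with its own staged fit;
* residual-bootstrap confidence intervals and Monte Carlo prediction
  bands;
* one-at-a-time ±60% sensitivity analysis identifying rate-limiting
  steps;
* a synthetic plate-reader data generator reproducing the study design
  (10 nmol/L DNAzyme, 100–1000 nmol/L substrate, 30 s readings, 25 min,
  replicated wells, pipetting and read noise), so the entire pipeline is
  testable end to end without access to the original raw data.

The methods vignette (`vignettes/dnazyme-kinetics.Rmd`) documents the
model, the estimation stages, all numerical choices, and a detailed
account of which parameters this study design can and cannot identify.

## Worked example

Simulate a reference curve, generate a synthetic replicated experiment,
and refit it:

```r
library(dzkin)

r <- reference_rates()      # literature point estimates, 55 °C, 20 mM Mg2+
r
#> DNAzyme rate constants (nmol/L, s):
#>     k_on    k_off    k_clv    k_lig    k_rls    k_bin
#> 0.004525 0.155500 0.222000 0.000000 20.650000 0.113000

tr <- simulate_reaction(r, s0 = 1000, e0 = 10, times = seq(0, 1500, 30))
tail(tr$observable, 1)      # nmol/L cleaved after 25 min
#> [1] 994.1406

cs  <- generate_curve_set(experiment_design(replicates = 8), seed = 42)
fit <- fit_kinetics(cs, "no_ligation", settings = fit_settings(seed = 1))
fit
#> DNAzyme kinetic fit (no_ligation)
#>       estimate      sd
#> k_on   0.03010 0.01520
#> k_off  2.66700 1.23000
#> k_clv  0.24120 0.06740
#> k_rls  2.86700 1.78000
#> k_bin  0.01386 0.00981
#> RMSE 11.92 nmol/L | AIC 10083.90 | 2000 obs, 85 params, 40 curves
```

The RMSE sits at the injected 2% measurement noise, i.e. the model
tracks every curve; the cleavage constant is recovered close to its
generating value (0.222 s⁻¹), while the binding/release constants land
on a quasi-equivalent ridge — the expected behavior for this design,
discussed at length in the vignette. Rank the rate-limiting steps:

```r
rank_sensitivity(sensitivity_analysis(r, s0 = 1000, e0 = 10,
                                      times = seq(0, 1500, 30)))
#>   constant     score rank
#> 1    k_clv 352.30140    1
#> 2     k_on 158.08492    2
#> 3    k_rls 124.56891    3
#> 4    k_bin  85.43423    4
#> 5    k_off  42.19001    5
```

Cleavage dominates, association is second, and dissociation/product
binding are the most robust steps (scores in nmol/L of worst-case
observable deviation under ±60% perturbation).

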