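# prenylflux

Quantitative metabolomics and ¹³C isotopologue profiling of isoprenoid
(mevalonate / prenyl-pyrophosphate) precursors.

`prenylflux` implements the computational side of a targeted LC–HRMS
workflow for the intermediates MEV, M5P, M5PP, IPP, DMAPP, GPP, FPP and
GGPP in engineered yeast: exact-mass calculation for targeted negative-mode
acquisition, correction of measured mass fractions for natural isotope
abundance and tracer purity, mean ¹³C-enrichment, logistic labeling
kinetics with half-times, absolute quantification by isotope dilution mass
spectrometry (IDMS) with LOD/LOQ/linear-range validation under the ±20%
rule, Welch comparisons between strains, and turnover-based relative flux
inference. Because raw instrument data are rarely at hand when developing
or validating such pipelines, the package ships a ground-truth-known
simulator of instationary ¹³C labeling, measurement noise,
internal-standard signals and calibration series, so every stage can be
exercised end to end. It is written for metabolomics/fluxomics
practitioners working in R; all user-facing functions take data frames and
return tibbles.

## The models at the core

**Mean ¹³C enrichment.** For a metabolite with *n* carbons and corrected
isotopologue fractions *M₀ … Mₙ* (Mᵢ = proportion of the species carrying
*i* ¹³C atoms),

    E = ( Σᵢ i·Mᵢ ) / n .

**Isotopologue correction.** Measured mass fractions are the product of a
lower-triangular operator and the tracer-derived distribution: nominal
species with *j* labels contribute `binomial(j, purity)` over their tracer
positions convolved with `binomial(n−j, 0.0107)` natural ¹³C on the
remaining carbons. `correct_spectrum()` inverts this by non-negative least
squares (high-resolution regime: only carbon isotopes need correcting).

**Labeling kinetics.** After a switch to U-¹³C-glucose at t = 0,
time-course enrichments are fitted with the logistic model

    E(t) = k·y₀·e^{t·T} / (k + y₀·e^{t·T} − y₀),

and the half-time — the time needed to exchange half of a pool's ¹²C atoms —
follows in closed form as

    T₅₀ = (1/T)·ln((k − y₀)/y₀),

at which E(T₅₀) = k/2 exactly.

**Turnover and flux.** A pool's labeling timescale is its turnover
(pool size / flux). When labeling dynamics are unchanged between strains,
flux scales with the pools, and the relative flux change equals the
pool-size ratio with delta-method error propagation.

## Worked example

Simulate a wild-type-like labeling experiment (11 sampling times over
120 min, 2 replicates, 5% measurement CV), correct the raw spectra, and fit
the labeling kinetics:

```r
library(prenylflux)
library(dplyr)

cfg  <- sim_config("WT", noise_cv = 0.05, replicates = 2, seed = 1)
meas <- apply_measurement_layer(simulate_labeling(cfg), cfg)
corr <- correct_measurements(meas)
enr  <- enrichment_series(
  filter(corr, metabolite %in% c("M5P", "IPP_DMAPP", "GPP", "FPP", "GGPP")))
fits <- fit_enrichment_kinetics(enr)
select(fits, metabolite, k, y0, T, t50, converged)
#> # A tibble: 5 × 6
#>   metabolite     k     y0     T   t50 converged
#>   <chr>      <dbl>  <dbl> <dbl> <dbl> <lgl>
#> 1 FPP        0.986 0.0140 0.308 13.8  TRUE
#> 2 GGPP       0.981 0.0156 0.245 16.9  TRUE
#> 3 GPP        0.987 0.0199 0.332 11.7  TRUE
#> 4 IPP_DMAPP  0.984 0.0267 0.390  9.17 TRUE
#> 5 M5P        0.978 0.0588 0.626  4.39 TRUE
```

Label incorporation follows pathway order — T₅₀ rises from ~4 min (M5P) to
~17 min (GGPP) — and the fitted plateaus k sit just below the 99% tracer
purity. Strain comparison from replicate summaries (GGPP pools in
nmol/gDCW, mean ± SD, n = 3):

```r
welch_test(1.4, 0.1, 3, 12.8, 2.0, 3)
#>       t    df p_value
#>   -9.86  2.01 0.00996
flux_ratio(12.8, 2.0, 3, 1.4, 0.1, 3)
#>   ratio    sd
#>    9.14  1.57
```

A 9.1 ± 1.6-fold higher GGPP pool with unchanged labeling dynamics means a
9.1-fold higher biosynthetic flux under constant turnover.

`autoplot()` methods exist for fitted kinetics and calibration curves, and
`run_pipeline()` orchestrates all stages (including IDMS quantification
against simulated calibration series) with provenance-stamped CSV outputs.
A thin command-line wrapper with `simulate`, `correct`, `enrich`,
`fit-kinetics`, `quantify`, `compare` and `run` subcommands is shipped in
`inst/cli/prenylflux.R`.

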