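---
title: "Methods: isotopologue profiling and IDMS quantification of isoprenoid precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopologue profiling and IDMS quantification of isoprenoid precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenylflux)
library(dplyr)
```

This vignette documents the scientific models behind `prenylflux`, the
assumptions they rest on, the tunable parameters, and the design choices
made where the design was genuinely open.

## The measured system

The mevalonate / prenyl-pyrophosphate pathway runs from acetyl-derived
two-carbon units through mevalonate (MEV, C6), mevalonate-5-phosphate
(M5P, C6) and mevalonate-5-pyrophosphate (M5PP, C6), loses one carbon in
the decarboxylation to isopentenyl pyrophosphate (IPP, C5), and then
elongates by successive condensation with IPP: GPP (C10), FPP (C15), GGPP
(C20). IPP and its isomer DMAPP are isobaric and co-elute, so they are
read out as a single 6-isotopologue signal while remaining two metabolic
pools — that is why the default configuration counts 61 isotopologues from
6 pools per timepoint (7 + 6 + 11 + 16 + 21), and 671 over the 11 sampling
times. MEV and M5PP are simulated but flagged non-quantifiable in labeling
experiments (low, variable signals); they remain quantifiable in the
metabolomics (IDMS) branch.

Exact [M−H]⁻ masses are computed from monoisotopic atomic masses (≥ 6
decimals) minus the proton mass 1.0072765 Da, which reproduces the
acquisition target masses to 5 decimals. Only the deprotonated species is
supported: all eight compounds are acids/phosphates measured in negative
mode.

## Isotopologue correction

At a resolving power of 70,000 with a 5 ppm extraction window, isotopic
peaks of elements other than carbon (¹⁸O, ²H; the compounds contain no N
or S) are resolved away from the ¹³C isotopologues, so only carbon natural
abundance and tracer purity are corrected — the high-resolution regime.
The forward operator maps the tracer-derived ("nominal") distribution to
the observed one; its column for the nominal species with *j* labels is

> binomial(j, purity) ⊛ binomial(n − j, a),  a = 0.0107,

i.e. purity applies to the *j* tracer positions and natural abundance to
the *n − j* substrate-derived carbons. We deliberately build each column
jointly rather than multiplying a purity matrix by an abundance matrix:
the matrix product would re-expose purity-failed tracer positions to
natural abundance, which is not how the two phenomena compose physically.
Inversion uses non-negative least squares (noise can drive an
unconstrained solution negative) followed by renormalization; the relative
residual is attached to the result and a residual above 5% warns (an
interfering peak or wrong carbon count) without failing.

Purity correction is applied per tracer position (binomial), the standard
convention; whether to apply it per position or globally is immaterial at
purity 0.99 for the conclusions drawn here but the per-position form is
exact for the simulator's own source model.

## The labeling simulator

The simulator exists so that every downstream stage has a ground truth.
It assumes metabolic steady state (constant pools, constant flux) and
isotopic non-steady state: for pool *i* with size *Pᵢ* (nmol/gDCW) and
pathway flux *f* (nmol/gDCW/min),

> d Mⁱ/dt = (f / Pᵢ) · (M_inflow − Mⁱ),

over isotopologue-distribution vectors. Inflows follow the chemistry:
threefold convolution of the two-carbon source distribution for MEV,
the upstream pool for linear steps, a random carbon-loss operator for the
decarboxylation (mass isotopologues carry no positional information, so
the lost carbon is uniform among the six — M′ⱼ = Mⱼ(n−j)/n + Mⱼ₊₁(j+1)/n),
and convolution of the substrate distributions for condensations. At t = 0
the source switches instantaneously from binomial(2, 0.0107) to
binomial(2, 0.99); an optional first-order `source_lag` models slower
glycolytic equilibration, and is off by default because upper-glycolysis
turnover is fast relative to this pathway.

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) with atol
1e-9 / rtol 1e-8; output distributions are clipped at 0 and renormalized.
The linear structure makes the system non-stiff in practice; the analytic
single-pool solution E(t) = p·(1 − e^(−t/τ)) is reproduced to 1e-6 in the
tests.

**Default pool sizes and flux are fixtures, not measurements.** Absolute
fluxes are not published for this system; we fix the wild-type GGPP pool
at the printed 1.4 nmol/gDCW, choose the remaining pools at comparable
sub-nmol/gDCW magnitudes (MEV 1.0, M5P 0.5, M5PP 0.4, IPP/DMAPP 1.0,
GPP 0.8, FPP 1.0), and set f = 0.3 nmol/gDCW/min so that noise-free
half-times span roughly 5 min (M5P) to 20 min (GGPP) across the pathway —
the experimentally observed window. The overexpression preset ("S037")
scales every pool and the flux by 12.8/1.4, which leaves all labeling
dynamics invariant (turnover unchanged); that invariance is itself a
tested property and is the mechanism behind reading flux changes off pool
changes.

### Measurement noise

Measured peak areas carry multiplicative lognormal noise with total CV
`noise_cv` (default 0.10), decomposed into a per-injection common-mode
factor shared by every peak of a sample — source fluctuations, injection
volume — and an independent per-peak residual with CV `peak_cv` (default
0.04, typical Orbitrap peak-area repeatability). The decomposition matters
for IDMS: the common factor multiplies analyte and ¹³C internal-standard
areas alike and cancels exactly in the ¹²C/¹³C ratio, which is the reason
isotope dilution is precise at all. Ratios therefore carry ≈ √2·`peak_cv`
noise. Calibration series additionally receive an additive blank floor
(`blank_sd`, ratio units) and saturate above 50 pmol on column, emulating
the upper end of the validated linear range.

What the generator does **not** emulate: chromatography and retention-time
drift, ionization suppression and matrix effects, in-source fragmentation
(the small M5PP→M5P interference is noted but not modeled), extraction
losses, and inter-day drift. Passing tests on simulated data therefore
validate the mathematics and the software contract of each stage — not the
instrument-dependent numbers (LODs, instrument precision), which can only
come from real calibration runs.

## IDMS quantification and validation

Quantification inverts a calibration line of ¹²C/¹³C ratio vs amount on
column, scales by resuspension/injection volumes (defaults 200 µL / 10 µL,
mirroring the sampling protocol) and divides by biomass. Calibration fits
use least squares with 1/x weighting by default: the range spans three
orders of magnitude, and with unweighted OLS the top level's *absolute*
noise (at 50–100 pmol, ~0.5 ratio units even at 5% CV) swings the
intercept by enough to bias the lowest levels by >20% and destabilize the
validated range. Unweighted OLS remains available (`weighting = "none"`).

Validation applies the ±20% rule: a level is accepted when its mean
back-calculated amount is biased by at most 20% and its replicate RSD is
at most 20%. The linear range is found by a widest-first search over
contiguous level windows, each window judged against the line fitted on
that window alone; ties at equal level count go to the span covering more
orders of magnitude. This construction prevents a saturated top level from
either joining the range or dragging the working curve. LOQ is the lowest
accepted level; LOD uses the 3σ/slope convention (Eurachem-compatible),
with σ from blank replicates when present, else the lowest level.

## Labeling kinetics

Enrichment time courses are fitted with the logistic model
E(t) = k·y₀·e^(tT) / (k + y₀·e^(tT) − y₀) by Levenberg–Marquardt
(`minpack.lm::nlsLM`) with a deterministic initialization: y₀ from the
first observation floored at 1e-4 (the model is undefined at y₀ = 0, and a
corrected pre-switch sample has E ≈ 0), k from the maximum observation
capped at 1, T from the log-linear early-phase slope, bounds
y₀ ∈ [1e-6, 1], k ∈ (0, 1], T ∈ (0, 10]. The half-time follows in closed
form, T₅₀ = ln((k − y₀)/y₀)/T, and satisfies E(T₅₀) = k/2 identically — a
property checked to 1e-9 on every returned fit. Series whose total
enrichment change is below 0.05 are flagged degenerate and excluded from
half-time comparisons, mirroring the exclusion of pools with low, flat
signals; fits that converge with y₀ ≥ k are likewise flagged rather than
producing a spurious T₅₀. Enrichments are fitted as fractions (T₅₀ is
invariant to the percent/fraction choice). Per-point SD weights can be
supplied when replicate series exist; the default is unweighted because
n = 2 biological replicates make per-point weights unstable.

## Strain comparison and flux ratios

Welch's two-sided t test is computed from (mean, SD, n) summaries with
fractional Satterthwaite degrees of freedom — integer rounding would
change reported p-values at n = 3. No multiple-testing adjustment is
applied; per-metabolite p-values are reported raw, matching how such
comparisons are usually published for a handful of pathway intermediates.

Under constant turnover, the flux ratio between strains equals the
pool-size ratio; its SD is propagated to first order assuming independent
groups, with a bootstrap alternative. The first-order SD of
12.8 ± 2.0 over 1.4 ± 0.1 is 1.6; published uncertainties for such ratios
can differ (e.g. when computed from per-replicate ratios), so both
estimators are exposed rather than guessing an undocumented convention.
When half-times are supplied, the turnover-adjusted ratio
(mean/T₅₀)_A / (mean/T₅₀)_B is used; on data generated with flux ∝ pool
the two modes agree within noise.

## Numerical and degenerate-input conventions

- Distributions are validated to sum to 1 within 1e-9 and be non-negative;
  the integrator's outputs are renormalized per timepoint.
- `correct_spectrum` rejects all-zero spectra; inconsistent spectra warn
  with the relative residual attached.
- `t50_logistic` returns a non-positive half-time with a warning (not
  clamped) when y₀ ≥ k/2: the pool was already half-exchanged at t = 0.
- Welch's test refuses n < 2 or two zero-variance groups.
- Calibration validation reports an absent LOQ as `NA`, never 0.

## Problem sizes

The shipped test-suite and acceptance computations use the study's actual
design sizes where they are defined (11 timepoints, 2–3 replicates, 8
compounds, calibration levels 0.02–100 pmol) and modest Monte-Carlo widths
(20–30 seeds) elsewhere, which characterize medians and rates without
excess computation.

## Known limitations

- Only mass isotopologues are tracked; positional isotopomers are out of
  scope (the decarboxylation operator assumes a uniformly random carbon).
- Only carbon correction is implemented; a low-resolution all-element
  correction mode would require resolution-dependent overlap modeling.
- The simulator's absolute scales (response factors, pool sizes other
  than GGPP, flux) are plausible fixtures; conclusions about instrument
  characteristics cannot be drawn from them.
- Non-stationary ¹³C metabolic flux analysis — estimating absolute fluxes
  from the transients — is deliberately not attempted; it needs dedicated
  models beyond constant-turnover reasoning.
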