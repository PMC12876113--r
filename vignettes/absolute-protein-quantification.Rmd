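---
title: "From relative fluorescence to absolute protein concentration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From relative fluorescence to absolute protein concentration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoquant)
```

## The problem

Fluorescent reporter proteins such as EmGFP are read out in relative
fluorescence units (RFU) — instrument-dependent, dimensionless numbers that
cannot be compared across devices, gains or laboratories. Process decisions
in precision fermentation, however, need absolute product titers in mg/L.
`fluoquant` implements a workflow that converts in-cell plate-reader RFU of
intact *E. coli* suspensions into absolute EmGFP concentrations by chaining:

1. **Standard-based linear calibration** of the fluorescence response,
   with an FDA-style validation battery (linearity, LOD/LOQ, spike
   recovery, intraday/interday precision);
2. **SDS-PAGE densitometry scaling**: the target band's share of its lane's
   total intensity apportions the independently measured host-cell-protein
   (HCP) concentration to the target protein, giving absolute mg/L anchors;
3. **An affine conversion model** `RFU = a * conc + b` fitted over the
   expression window from inoculation to the RFU maximum, with a hard
   validity range beyond which conversion is refused;
4. **Control-strain background assessment** (signal-to-background ratio,
   autofluorescence per biomass) and an **in-cell vs. lysate correlation**
   that justifies quantifying intact cells directly.

## Model and assumptions

### Calibration, LOD and LOQ

The calibration is ordinary least squares of instrument response on nominal
concentration. Detection limits follow the standard response-SD formulation

$$\mathrm{LOD} = 3.3\,\sigma / S, \qquad \mathrm{LOQ} = 10\,\sigma / S,$$

where $S$ is the calibration slope and $\sigma$ is, by default, the sample
standard deviation (n−1) of the replicate responses at the lowest non-blank
level. A `sigma_mode = "residual"` option uses the regression residual SD
instead; the replicate-SD definition is the primary one because the lowest
standard is where detection is actually decided, and it is what
`validate_method()` reports. `LOQ/LOD = 10/3.3` holds identically because
both derive from the same $\sigma$ and $S$.

### The conversion model and its validity range

`fit_conversion()` regresses cell-suspension RFU on absolute concentration.
The anchoring concentrations come from gel densitometry:
`target = (lane% / 100) × HCP`, where lane% is the target band's share of
all bands in its lane (band matching within ±2 kDa of the 27 kDa apparent
target size) and HCP is the Bradford-basis total soluble protein on the same
culture-volume basis. Because both quantities refer to the same lysate, load
volume and sample-to-buffer ratio cancel and are carried only as metadata.

The fitted line is only trusted inside the observed calibration range:
`rfu_valid_max` is the largest RFU used in the fit, and `rfu_to_conc()`
throws a classed range error — carrying the power-of-two dilution factor
that would bring the reading back into range — rather than extrapolating.
Readings below the fitted intercept clamp to 0 mg/L with a
`below_calibration` flag.

Plate-reader noise is scale-proportional (approximately constant CV), so the
pipeline fits the conversion with inverse-squared-response weights, the
conventional weighting for bioanalytical calibration across a wide dynamic
range; `fit_conversion()` defaults to the unweighted fit so that it matches
the closed-form least-squares solution exactly.

### Background and the in-cell shortcut

Quantifying intact cells is only legitimate if (a) the plasmid-free control
strain's autofluorescence is a small fraction of the producer signal and
(b) the in-cell signal tracks the post-lysis signal. `assess_background()`
reports the per-phase mean signal-to-background ratio S/F′, the raw
background means, the biomass-specific autofluorescence F′/X′, and the
maximum background fraction 100·F′/S over all timepoints.
`fit_incell_vs_lysate()` reports the regression of in-cell on lysate RFU and
the maximum relative deviation |cell − lysate|/lysate, excluding timepoints
whose lysate signal sits below a configurable low-signal floor (relative
deviations explode near zero signal). The deviation is declared negligible
at or below 12%, the level at which in-cell readings are used directly.

## The synthetic generator

No measurement data ship with the package; every stage is exercised against
a seeded generator (`simulate_cultivation()` and friends) whose defaults
*are* the study conditions the workflow targets:

| Parameter | Default | Meaning |
|---|---|---|
| `x0`, `x_max` | 0.0334, 3.23 g/L | inoculum (OD 0.1) and peak biomass |
| `mu` | 0.40 h⁻¹ | specific growth rate |
| `glucose0`, `yield_xs` | 10 g/L, 0.323 g/g | batch substrate and yield |
| `hcp_fraction` | 0.40 | soluble HCP as fraction of biomass |
| `target_fraction` | 0.1527 | target protein as fraction of HCP |
| `conv_slope`, `conv_intercept` | 4837.0, 8697.6 | cell-suspension RFU per mg/L |
| `quench_incell` | 0.95 | in-cell attenuation vs. lysate |
| `autofl_per_biomass` | 1.5×10³ RFU per g/L | control-strain autofluorescence |
| `decay_rate` | 0.02 h⁻¹ | post-depletion product decay |
| `cv_rfu`, `cv_gel`, `cv_hcp` | 2%, 5%, 5% | observation CVs |
| `std_slope` | 778.5 RFU per mg/L | cell-free standard-curve response |

Growth is exponential with a hard carrying cap tied to substrate
stoichiometry (`glucose = glucose0 − (X − x0)/yield_xs`, floored at zero);
Monod kinetics would add nothing for testing the quantification layer. With
these defaults the biomass cap is reached just before the substrate would
run out, so glucose floors at ~0.1 g/L rather than exactly zero; the
generator therefore treats glucose below `depletion_glucose` (default
0.5 g/L, the practical quantification floor of the glucose assay) as
depleted. Production tracks biomass until depletion and then decays
first-order, emulating proteolytic degradation after substrate exhaustion.

The conversion coefficients parameterise the **cell-suspension** response —
that is the relationship the method ultimately fits — and the lysate signal
is derived by dividing out the in-cell attenuation:
`rfu_lysate = (conv_slope/quench_incell)·conc + conv_intercept`. The
control strain carries no target protein; its signal is
`autofl_per_biomass × X` only. The inoculum already carries target protein
in proportion to biomass, which keeps the background fraction below 4% at
every timepoint including t0 — a property the method requires by
construction; real pre-induction cultures need not satisfy it.

Observation noise is multiplicative lognormal (plate-reader noise is
scale-proportional), parameterised so replicate means are unbiased, with
seeds as explicit function arguments that never touch global RNG state.
The standard-curve response slope (778.5 RFU per mg/L) is deliberately
distinct from the conversion slope: standards are measured cell-free in the
plate, while the conversion maps culture-volume concentrations, so the two
responses differ by the measurement basis. Interday precision draws a
shared lognormal day effect (`cv_day`, default 3%) on top of per-reading
noise; the generator needs *some* between-day model and a few percent is
typical plate-reader day-to-day drift. CFU plating uses Poisson counts with
a cells-per-OD factor of 8×10⁸ mL⁻¹ (the usual *E. coli* rule of thumb) and
auto-selects the decade dilution that lands in the 30–300 countable window.

**What passing tests show — and what they do not.** The generator reproduces
the *statistical structure* the framework assumes: linear responses,
constant-CV noise, proportional production, a clean control strain. Passing
the battery on it demonstrates the estimators are correct and the workflow
is internally consistent; it does not demonstrate that a particular real
assay is linear, that real autofluorescence is negligible, or that real
matrix effects vanish — those are exactly the properties the validation
battery must establish per laboratory setup.

## Numerical and design choices

* **Dilution labels.** `"1:n"` is an n-fold *total* dilution (stock/n),
  the convention under which 12.6 g/L diluted 1:100 is 126 mg/L. Nominal
  concentrations, not labels, are authoritative when both are given.
* **Sodium fluorescein mass.** The shipped Na-F* spec uses the disodium
  salt (376.27 g/mol), the only mass consistent with 1 µM ≡ 0.376 mg/L;
  the free acid would give 0.332 mg/L.
* **OD to biomass.** `biomass = 0.334 × OD600`. Only this direction
  reproduces a ~3.23 g/L peak biomass at plausible batch OD; the factor is
  configurable everywhere it is used.
* **Saturation gating.** Readings above 49,000 RFU get the smallest
  power-of-two PBS dilution that clears the gate — minimal and reproducible.
  The plan acts on the raw (blank-inclusive) reading, since that is what
  saturates the detector.
* **Blank correction** clamps at zero with a flag; negative RFU are never
  reported.
* **Rounding.** All computation and JSON serialisation is unrounded;
  3-significant-figure rounding happens only in Markdown display.
* **Recovery** is `(spiked − unspiked)/added × 100`, the standard-addition
  form. Spike pairs measured at mismatched pH can be flagged and set aside
  rather than silently pooled, because fluorescein's response collapses at
  neutral pH while EmGFP's collapses at pH 13.
* **Intraday threshold.** The guideline battery passes intraday RSD at
  ≤10%; the generator's own conditions achieve <5%. All four thresholds are
  user-configurable in `validation_thresholds()`.
* **Triplicate pooling.** `run_pipeline()` pools the conversion-fit points
  from three replicate cultivations (matching a triplicate study design):
  a single 7-point fit leaves the small intercept (~8.7×10³ RFU against
  peak signals of ~10⁶) statistically unidentifiable at realistic noise.
* **Degenerate inputs.** Fewer than 3 distinct concentration levels, zero
  concentration spread, or a non-increasing conversion response raise
  classed `fluoquant_degenerate_design` errors; a saturation gate that
  rejects every calibration reading aborts the pipeline with an actionable
  message rather than silently fitting re-measured noise.

## Problem sizes

The test-suite and acceptance computations run on the generator's native
scale: 13 timepoints (24 h sampled every 2 h), 8-level triplicate standard
curves, 4 spike levels × 3 replicates, 3-day × 3-replicate precision
studies, and 3 pooled cultures for the conversion fit. A full
`run_pipeline()` call takes well under a second.

## Known limitations

* Gel densitometry starts from band-intensity tables; pixel-level image
  analysis is out of scope.
* The conversion model is affine and assay-specific: changing instrument,
  gain, strain, media or temperature requires re-establishing it.
* Inner-filter effects, fluorophore maturation kinetics and photobleaching
  are summarised into a single scalar in-cell attenuation; the framework
  checks that this is small, not why.
* The generator's growth model is deliberately minimal (capped exponential,
  stoichiometric substrate); it is a test harness for the quantification
  layer, not a process model.
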