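---
title: "Methods: single-particle ICP-MS data reduction and survey statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle ICP-MS data reduction and survey statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotrace)
```

# The measurement model

Single-particle ICP-MS acquires one integrated detector reading per dwell
interval. Two signal sources superimpose:

* a **dissolved background** — analyte ions, spectral interferences and dark
  counts — whose reading in a dwell is well described as Poisson with a
  slowly varying mean λ (counts/dwell);
* **particle transients** — a nanoparticle vaporized in the plasma produces
  an ion cloud that the detector sees as a burst spanning one to several
  dwells. At the 100 µs dwell time used throughout, a typical transient
  (several hundred µs) covers 3–7 dwells.

The reduction problem is to decide which excursions above background are
particles, to integrate them, and to convert integrals into element masses
and concentrations through calibration.

## Baseline and threshold

`rollingMedianBaseline()` estimates λ per dwell as the median of a centred
window (default 1001 dwells ≈ 0.1 s). The median is insensitive to the
sparse, short transients riding on the background, yet follows instrumental
drift on the 0.1 s scale and above. At the trace edges the window shrinks
symmetrically, down to a single dwell at the first/last position.

`poissonThreshold()` implements the false-positive-rate criterion: the
threshold is the smallest integer count `T` whose exceedance probability
under `Poisson(λ̂)` is at most `fpRate × dwellTime / 60`, so that pure noise
is expected to produce at most `fpRate` spurious events per minute of dwells
(default 1/min). Two numerical choices matter:

* λ̂ enters as a real number — no integer rounding — which avoids threshold
  quantization when the baseline sits between integers;
* when `detectEvents()` computes the baseline itself, the rate entering the
  threshold is guarded in two places where a median cannot estimate a rate.
  Near the edges (within half a window) the shrunk windows degenerate to a
  handful of dwells — a median of three Poisson(1) counts is frequently 0 —
  so the first/last full-window baseline value is used there. And globally,
  the threshold rate is floored by a robust background estimate (the trace
  mean after iteratively excluding above-threshold dwells): the median of
  Poisson counts at a rate below ≈ 0.7 is 0 *regardless of the rate*, so at
  low backgrounds the rolling median alone would set `T = 1` everywhere and
  flag every stray count. The shrunk/unfloored median remains the
  integration baseline. With both guards the empirical false-positive rate
  on particle-free noise sits at ≈ 1/min across backgrounds from 0.1 to 10
  counts/dwell (measured by the test suite and `scripts/acceptance.R` over
  ≥ 10 simulated minutes per level).

## Segmentation and integration

Candidate peaks are maximal runs of dwells strictly above the local
baseline; runs separated by at most `gapMerge` (default 2) sub-baseline
dwells are merged, so a single-dwell dropout inside a transient does not
split an event. A candidate is retained iff its maximum raw count reaches
the threshold computed from the baseline at that maximum — maximum-peak
discrimination, rather than an area criterion. The event integral is
`Σ max(counts − baseline, 0)` over the span; clipping at zero prevents noise
troughs inside an event from subtracting signal. Segmentation rules of this
kind are not uniquely fixed by the false-positive criterion; both `gapMerge`
and the window are exposed as configuration, and the defaults are validated
against the package's own simulator (split-trace consistency, ≥ 0.99 recall
on events with peaks at twice the threshold).

Fully coincident particles are *not* deconvolved: two particles arriving
within one merge window are counted once, with summed mass. This is a
stated non-goal; its practical consequence is quantified below.

## Calibration and mass conversion

A dissolved standard at concentration `C` µg/L produces `a + bC` counts per
dwell; `fitIonicCalibration()` fits `a`, `b` by ordinary least squares over
all supplied standard runs (three concentrations including 0, start- and
end-of-day runs pooled). During one dwell, `η · q · t_dwell · C` micrograms
of analyte reach the plasma (`q` the uptake in L/s, `η` the transport
efficiency), so the detector response is `b / (η q t_dwell)` counts per
microgram, and an event of integral `S_p` carries

$$m_p = \frac{S_p\, \eta\, q\, t_\mathrm{dwell}}{b}.$$

Internally all masses are in grams, volumes in litres and times in seconds,
converted once at the user interface (flow in mL/min, concentrations in
µg/L, masses reported in fg where conventional).

`transportEfficiencyFrequency()` determines `η` as detected particles over
delivered particles for a reference suspension of known number
concentration (the monodisperse 60 nm gold reference: number concentration
= mass concentration / single-particle mass, `goldReference()`).
`transportEfficiencyMass()` solves the mass equation for `η` using the mean
reference integral. The frequency method is the default: it needs no ionic
calibration and is unbiased as long as counting is complete. The mass
method serves as a cross-check; the pipeline logs both. Consistency checks
run the reference at 125 ng/L — a 1:10 dilution of the conventionally
prepared 1250 ng/L stock — because at full strength a 45 s acquisition
carries ≈ 10⁴ events (≈ 12% dwell occupancy) and coincidence losses of
several percent would dominate the comparison; at 1:10 the occupancy is
≈ 1% and the loss is far below counting error. Diluting the reference until
particle events are clearly separated is standard practice for exactly this
reason.

`massEquivalentDiameter()` converts mass to the diameter of a sphere of the
assumed compound: `d = (6 m_p / (f π ρ))^{1/3}`. Density ρ and element mass
fraction f are *assumptions about speciation*, not measurements — reported
sizes are mass-equivalent diameters under that composition.

## Concentrations, blanks and limits

The analysed digest volume is `η · q · t_acq` litres (only the transported
fraction counts particles), so `n` events give `n / (η q t_acq)` particles
per litre of digest, divided by the dilution (grams of tissue per litre,
default 1) for per-gram values; mass concentrations use the summed event
masses. `blankSubtract()` removes the mean of matching procedural blanks at
the concentration level and floors negative results at zero with a flag —
concentrations are non-negative, and the flag preserves the information
that the blank exceeded the sample.

`detectionLimits()` derives, per analysis day, concentration LOD/LOQ as
blank mean + 3/10 sample SD and averages them across days; the
mass-per-particle LOD converts the day's intensity threshold through the
mass equation and takes the *maximum* across days, so that the
false-negative rate of the pooled data set is bounded by the worst day. The
3σ/10σ convention follows the package's total-element rule
(`totalLod()` = 3 × SD of 12 procedural blanks; 6 for Ag, whose blank set
is smaller); sample (n−1) SDs are used throughout because blank sets are
small. Two orderings were genuinely open — whether LOQs use 10σ and whether
blank subtraction precedes limit determination; the package subtracts
first and uses 10σ, and both choices are localized in `detectionLimits()` /
`applyLimits()`.

Total element analysis (`totalConcentration()`) converts digest intensity
through the same calibration, scales by digest volume over dry mass, and
multiplies by the dry-weight fraction to express results per gram wet
tissue. Detection limits are applied on the dry basis and converted
alongside. Censoring propagates: a particle fraction
(`particleFraction()`) or correlation (`particleTotalCorrelation()`) is
only computed from pairs in which neither operand is below its detection
limit.

# Survey statistics

`summarizeSurvey()` works on location means of triplicate parallels,
computed over uncensored parallels; a location is censored when no parallel
is uncensored or its mean does not exceed the element's LOD. The summary
reports mean, min–max over uncensored locations, and the percentage of
locations above the LOD.

`surveyPca()` and `wardCluster()` use z-scored location means, with two
censoring modes: `"drop"` removes elements censored in more than half the
locations and imputes the remaining censored cells at LOD/√2 (the standard
substitution for left-censored lognormal-like data); `"impute"` keeps all
elements. By default concentrations are log10-transformed before
standardization: environmental concentrations are lognormal-like over an
order of magnitude or more, and a raw-scale z-score lets one or two extreme
sites dictate the rotation. The raw scale remains available
(`transform = "identity"`).

PCA is the eigendecomposition of the covariance of the standardized matrix
(`stats::prcomp`); loadings are orthonormal to machine precision and
explained-variance fractions sum to 1 by construction (both are asserted in
the tests rather than assumed). Group mean ellipses use the bivariate
normal approximation of the centroid: within-group score covariance divided
by the group size, scaled by the χ² quantile at 0.95 with 2 degrees of
freedom.

Ward clustering uses `stats::hclust(method = "ward.D2")` on Euclidean
distances — the minimal-increase-of-sum-of-squares method in the convention
where two singletons at Euclidean distance `d` merge at height `d`, i.e.
heights are `sqrt(2 ΔSSQ)`. Two height conventions circulate for "Ward";
they share the topology and differ only in the height scale, so the
convention is stated here and pinned by a test that reproduces merge orders
*and* heights by exhaustive enumeration of sum-of-squares increases on
small instances. Seasons, where used for grouping, derive from the
sampling month (DJF/MAM/JJA/SON); the data themselves do not define season
boundaries.

# The synthetic generator

`simulateTrace()` emulates the acquisition: homogeneous Poisson particle
arrivals with expectation `C_num · q · t_acq · η`, lognormal diameters
(median, geometric SD), masses via the sphere model, expected counts via
the same response relation the reduction inverts, spread triangularly over
a 3–7 dwell transient, plus a (optionally drifting) Poisson baseline — one
Poisson draw per dwell of the summed expectation. Every draw is controlled
by a single integer seed, and the ground truth (event positions, spans,
masses, true η, true response) is returned alongside the trace.

What it deliberately does **not** model: detector dead time and dual
analog/pulse stages, flicker (multiplicative) noise beyond sinusoidal
drift, incomplete vaporization of large particles, and coincidence
*resolution* (overlapping arrivals are recorded individually in the truth
but appear merged in the trace). Consequently, passing recovery tests show
that the reduction inverts this idealized physics correctly — they do not
certify accuracy on a real instrument, where dead time and size-dependent
ionization add biases the simulator cannot expose. The transient-duration
default (3–7 dwells) is a configuration choice, not an instrument
constant.

`simulateSurvey()` emulates the survey layer: 69 locations split
47 farm / 18 anthropogenic / 4 natural, triplicate parallels, eleven
elements with typical number concentrations and per-particle masses, and a
lognormal hierarchy — a shared per-location *site burden* factor
(`siteSdlog`, default 0.6) applied to all elements, element-specific
location noise (0.5) and parallel noise (0.2). The site factor is what
makes elements correlate within a location, as real surveys show (samples
from one site share elemental composition); without it, eleven independent
standardized columns give PCA nothing systematic to find, and
group-recovery properties would hinge on noise. Total between-location
spread (≈ 0.78 log-SD) matches the order-of-magnitude ranges typical of
coastal surveys. Class and season effects are multiplicative and
user-specified; detection limits sit at a configurable quantile of the
marginal distribution, and cells below them are flagged censored.

# Problem sizes and runtime choices

The unit tests run on shortened acquisitions (1–5 s; the physics is scale
free), keeping the suite at ≈ 20 s. The statistical checks use the full
45 s geometry: false-positive control over 10.5 simulated minutes
(14 acquisitions), end-to-end recovery at 3 × 10⁴ particles/mL — ≈ 560
events per acquisition, chosen so that coincidence losses (≈ 1%) stay an
order of magnitude below the `3/√N` sampling band — over five seeds, and
transport-efficiency consistency on the diluted reference (≈ 1000 events).
The mass-conservation check uses a 450 s acquisition (≈ 5600 events), where
the Monte-Carlo error of the mass sum is ≈ 1.5% against a 5% band.
`scripts/acceptance.R` recomputes all of these from scratch in well under a
minute.

# Known limitations

* No deconvolution of coincident particles: at high number concentrations
  counting is biased low; keep occupancy low (dilute) as in practice.
* The upper size limit (incomplete ionization) and the dissolved fraction
  of the baseline are not modelled or quantified.
* Ionic calibration assumes linearity over 0–200 µg/L.
* PCA/clustering inputs impute residual censored cells at LOD/√2; with
  heavy censoring the multivariate picture degrades gracefully but is not
  a censored-likelihood treatment.
* The survey generator's element scales are typical magnitudes, not a
  reproduction of any particular data set; tests assert recovery of the
  generator's own ground truth.
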