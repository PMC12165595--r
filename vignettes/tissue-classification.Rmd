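---
title: "Classifying airway tissue from reflectance spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying airway tissue from reflectance spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayspec)
```

## The problem

An endotracheal tube placed in the esophagus instead of the trachea, and not
noticed, harms patients within minutes. Diffuse reflectance spectra collected
through a fiber sensor at the tube cuff can tell the two tissues apart:
oxyhemoglobin in the well-perfused, optically thin tracheal mucosa imprints a
pronounced trough-peak-trough signature on the visible reflectance spectrum,
with absorption troughs near 543 and 578 nm flanking a local reflectance peak
at 561 nm. The esophageal wall shows the same signature much less strongly.
`airwayspec` implements the full analysis chain from raw spectrometer counts
to a classified tissue label with a percentage confidence, plus a synthetic
data generator that emulates the acquisition so the chain is testable end to
end.

## The processing model

Raw counts are converted to reflectance with paired references acquired in
the same session:

\[ R(\lambda) = \frac{\text{raw}(\lambda) - \text{dark}(\lambda)}
                     {\text{white}(\lambda) - \text{dark}(\lambda)}. \]

The references must strictly dominate (`white > dark`) inside the 535–585 nm
analysis band; there a violation is fatal. Outside the band a degenerate
point is merely flagged non-finite, because nothing downstream reads it — any
accidental lookup raises instead of returning garbage.

Each reflectance spectrum is then divided by its value at 561 nm, so the
central peak equals 1 and between-tissue variance concentrates in the two
troughs. The classification features are the normalized reflectance at the
trough wavelengths,

\[ x = (r_{543},\, r_{578}), \]

where smaller values mean deeper troughs, i.e. a stronger oxyhemoglobin
signature. All three wavelength lookups use linear interpolation between the
bracketing grid pixels rather than nearest-pixel reads. Real spectrometer
grids never land exactly on 543/561/578 nm and are not uniform; interpolation
makes the features independent of the grid pitch (the interpolation error is
bounded by pitch²/8 times the local curvature, about 4 × 10⁻⁵ at a 0.5 nm
pitch for the default trough widths — negligible against the class contrast).
Whether the original instrument analysis read nearest pixels or interpolated
is not knowable from the outside; interpolation is the choice here because it
is grid-invariant, and the tests exercise it on a jittered non-uniform grid.

No smoothing, baseline drift, or scatter correction is applied: the
acquisition already limits averaging to the spectrometer's own settings, and
the peak normalization removes overall intensity scale (the features are
invariant to multiplying counts and references by any positive constant).

## Classifiers and confidence

**K-nearest neighbor.** Minkowski distance of order `p` (default 2,
Euclidean — the standard default and consistent with a circular
neighborhood; `p` is a knob) on the 2-D features. Under the resubstitution
protocol a cohort point's voting set is itself plus its `k = 10` nearest
other points, i.e. 11 votes; confidence is the majority fraction in percent,
so 8 tracheal votes of 11 give "trachea, 72.7%". For external queries or the
leave-one-out protocol the voting set is the `k` neighbors alone. Distance
ties straddling the k-th rank are resolved by admitting the lexicographically
smallest (pair_id, organ, acq_index) — deterministic across runs and
platforms. An even voting set that splits equally falls back to the single
nearest neighbor's class, flagged and at 50% confidence.

**Linear discriminant.** Two-class Fisher LDA with equal priors (the cohort
design is balanced 450/450; an empirical-prior option exists):
\(w = S^{-1}(\mu_{eso} - \mu_{tra})\), \(b = -w\cdot(\mu_{eso}+\mu_{tra})/2\)
on the pooled within-class covariance \(S\), with the sign fixed so the
tracheal side of the boundary is negative. A point exactly on the boundary is
classified trachea by convention — in this application the costly error is
calling an esophageal placement tracheal, so the symmetric 50/50 case is the
user-visible "lowest confidence" outcome either way, and a fixed rule keeps
runs deterministic.

LDA confidence maps perpendicular boundary distance
\(d = |w\cdot x + b|/\lVert w\rVert\), normalized by the largest training
distance \(d_{max}\), through the exponential

\[ \text{conf}(u) = 100\, e^{\kappa (u - 1)}, \qquad
   u = \min(d/d_{max}, 1), \quad \kappa = \ln(100/63), \]

which is the minimal exponential through the two anchor points: 100% for the
furthest training point and 63% on the boundary. Only those endpoints are
externally fixed; κ is a knob. Distances beyond \(d_{max}\) saturate at 100%.

**Evaluation.** Accuracy; a confidence-calibration mean-square error where
the per-spectrum error is the assigned true-class probability's deviation
from 1 (`1 - conf/100` when correct, `conf/100` when wrong); and
`PSNR = 10 log10(1/MSE)` with peak 1 on the probability scale (MSE 7.4 × 10⁻³
↔ 21.3 dB). The error definition is this package's reconstruction — the
quantity is not standardized — but the PSNR form is pinned by that
arithmetic. A perfect cohort has MSE 0 and reports an explicitly flagged
infinite PSNR rather than a number. The cohort-level correctness claim uses
the exact Clopper–Pearson lower bound: for all `n` correct it is
`(α/2)^(1/n)`, e.g. 99.6% for 900/900 at α = 0.05. Exact rather than
Wilson/normal because the all-successes case — the case this design produces
— is exactly where approximate intervals are worst. Every rendering of the
bound carries the caveat that it assumes independent observations; 50 spectra
from one organ are not independent, so the true bound is lower.

Resubstitution is the default cohort protocol (it is what the inclusive
11-vote scheme describes); `protocol = "loo"` gives leave-one-out for honest
generalization estimates. Note that leave-one-out removes only the point, not
its 49 siblings from the same organ, so organ-level information still leaks;
a grouped (leave-one-organ-out) protocol would be the next step for real
data.

## The synthetic generator

`simulate_cohort()` emulates the acquisition: a 470–850 nm broadband source
envelope (two broad Gaussians, peak 50 000 counts above dark), a dark
reference at 100 ± 2 counts, and per-organ tissue reflectance

\[ R(\lambda) = B(\lambda)\,\bigl(1 - d_{543} G(\lambda; 543, 9)
   - d_{578} G(\lambda; 578, 11)\bigr), \]

with unit-height Gaussian troughs and a gentle quadratic baseline
\(B(\lambda)\) whose variation across the feature window stays under 10⁻³
after normalization. Trough centers sit at the feature wavelengths
themselves (543/578 nm rather than literature oxyhemoglobin band centers at
542/577 nm) so that the features read the trough minima; the centers are
configurable for robustness tests. Mean class depths default to (0.35, 0.40)
for trachea and (0.12, 0.15) for esophagus — calibration choices that
reproduce the qualitative contrast of a pronounced versus less pronounced
signature and make the default cohort linearly separable, matching the
ex vivo outcome; they are not measured values. Depth variability is
lognormal (depths must stay positive): one factor per (pair, organ) with
σ = 0.10 for between-animal spread, one small per-spectrum jitter with
σ = 0.02 for contact/position variation along the organ. Detector noise is
multiplicative Gaussian with σ = 0.01 (shot-like noise dominates at these
count levels). The acquisition design defaults to 9 pairs × 2 organs × 50
spectra = 900, and the whole cohort is a pure function of the config seed.

What the generator does **not** emulate: photon transport (no Monte Carlo, no
source–detector-distance dependence), pressure/contact artifacts, blood
contamination, specular reflections, wavelength-dependent detector response
beyond the smooth envelope, or between-sensor variation. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline arithmetic* is
correct and that the classifiers behave as designed on data with the assumed
statistical structure — they say nothing about how separable real in vivo
tissue is.

```{r example}
cfg <- run_config(simulate = simulation_config(seed = 1))
report <- run_pipeline(cfg)
report
```

## Numerical and design notes

- **Degenerate inputs.** Every malformed dataset is rejected with a classed
  error (`airwayspec_format_error`, `airwayspec_validation_error`, ...);
  nothing is coerced. A cohort too small for a classifier's precondition
  (K-NN needs `k + 1 <= n`; LDA needs two points per class and a nonsingular
  pooled covariance) is not an error at the pipeline level: the classifier is
  skipped with a typed notice and the report still renders.
- **Determinism.** Identical config (including the seed) produces
  byte-identical datasets and per-spectrum tables; the simulator saves and
  restores the caller's RNG state. All tie-breaks (k-th-rank distance ties,
  even vote splits, zero discriminant) are fixed, documented rules.
- **Chance-level validation.** The generator's separation dial is validated
  at both ends: with all variability at zero the classifiers are exactly
  100% correct, and with equal class depth means for every organ (the
  exchangeable null: `organ_depth_sd = 0` so no realized organ-level class
  difference exists) mean LDA resubstitution accuracy over 20 seeds sits
  near 50%. With organ-level depth clustering left on, equal *configured*
  means still yield realized per-organ differences, and resubstitution (or
  even leave-one-out) accuracy sits near 60% — a deliberate illustration of
  the within-organ dependence the confidence-interval caveat warns about,
  not a failure of the null.
- **Problem sizes.** The test suite exercises cohorts up to the full 900
  spectra and property checks on 200-point feature sets (K-NN oracle
  equivalence for p ∈ {1, 2, 3}), exact-interval agreement with a tail-sum
  bisection for all outcomes up to n = 50, parameter recovery over 50
  independent organ draws per class, and a 20-seed null sweep — sizes chosen
  to probe each property well past its small-sample regime while keeping the
  suite quick to run routinely.
- **Worked anchor values.** The suite pins the arithmetic to externally
  checkable anchors: 8/11 votes → 72.7%, MSE 7.4 × 10⁻³ → 21.3 dB,
  900/900 → 99.6% lower bound, boundary → 63% / furthest point → 100%.

## Limitations

Real instrument data arrive in vendor formats this package deliberately does
not parse; ingest expects the documented long-format CSV dialect. The MSE/
PSNR confidence-calibration metrics depend on the confidence mappings' free
parameters (k, κ) and are comparable only within a fixed configuration. The
exact binomial bound overstates certainty for repeated-measures cohorts, as
flagged in every report. And the headline 100%/100% separation on the default
synthetic cohort is a property of the calibrated generator as much as of the
classifiers; harder presets (smaller depth contrast, larger spread) exist
precisely to break it.
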