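---
title: "Quantifying the myoid sub-band posterior to the ELM: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the myoid sub-band posterior to the ELM: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsubband)
```

## The problem

On standard clinical OCT (5–7 µm axial resolution) the region between the
external limiting membrane (ELM) and the ellipsoid zone (EZ) — the myoid
zone — appears uniformly hyporeflective. High-resolution spectral-domain
OCT (~2.7 µm axial PSF FWHM), combined with fusion of repeated volume
scans, resolves a faint hyperreflective **sub-band** a few micrometres
posterior to the ELM, attributed to the photoreceptor myoid. Its salience
varies with age.

`octsubband` implements the quantitative analysis of that sub-band end to
end: because no raw patient volumes are publicly available, every stage is
driven by a parametric synthetic simulator whose defaults encode the
published study conditions, so that the measurement and statistics code is
testable without any download.

Two complementary readouts are produced, mirroring how such a faint feature
is assessed in practice:

* **A-scan ratiometry** — the peak intensity of the sub-band divided by the
  peak intensity of the ELM on the same A-scan, in linear scale, expressed
  in percent. The ELM is the natural reference: physically adjacent and
  consistently identifiable, with an intensity on the same scale.
* **B-scan visibility grading** — a categorical call (visible / not visible
  / cannot determine) per location, decided by majority over three graders.

## The forward model

An A-scan is a sum of Gaussian bands on the axial grid (0.89 µm/pixel),
flattened so that Bruch's membrane sits at a fixed row (depth increases
posteriorly; band centres are stored as negative anterior offsets from
Bruch's):

| band | centre (µm from BrM) | amplitude (a.u.) | intrinsic σ (µm) |
|---|---|---|---|
| ELM | −50 | 1.0 | 0.6 |
| sub-band | ELM + offset | ELM × relative reflectivity | 0.6 |
| EZ | −36 | 1.4 | 1.2 |
| RPE–Bruch's | 0 | 1.8 | 4.0 |

The instrument's axial PSF is Gaussian with FWHM 2.7 µm; each band's
effective width is `sqrt(intrinsic² + (FWHM/2.3548)²)`. The EZ centre
leaves a hyporeflective "inner ellipsoid" gap posterior to the sub-band;
its amplitude is unprinted anywhere, so an ELM-like brightness was chosen
from the appearance of published B-scans.

Key tunables and their defaults:

* `elm_subband_offset_um` — per-eye axial distance from the ELM peak to the
  sub-band peak. Drawn from a **shifted log-normal** that matches the
  published median (4.9 µm) and both quartiles (4.5, 5.6 µm) exactly
  (shift ≈ 3.97 µm), truncated at 8 µm. The truncation is an anatomical
  consistency bound: the sub-band is a myoid feature and must stay well
  anterior to the EZ (14 µm posterior to the ELM in this geometry). A plain
  2-parameter log-normal cannot reproduce the printed right-skewed
  quartiles and, worse, has a heavy left tail that generates eyes whose
  sub-band is unresolvable even at 2.7 µm — not a feature of the reported
  population.
* `speckle_shape` (default **64**) — speckle is multiplicative unit-mean
  gamma noise, i.i.d. per pixel per virtual acquisition; volume fusion
  averages `n_fused_volumes = 6` realizations. Fully developed speckle
  (shape 1) with only six averages would give peak-intensity CV ≈ 41%,
  irreconcilable with the smooth fused linear-scale A-scan profiles shown
  in print and with the published per-group ratio SDs (9–19 points). The
  default gives a fused peak CV ≈ 5%, consistent with the displayed
  profile smoothness. Set `speckle_shape = 1` for raw-speckle experiments,
  `Inf` for noiseless renders.
* Fusion is drawn in one pass: the mean of *n* i.i.d. `Gamma(s, scale
  1/s)` draws is exactly `Gamma(ns, scale 1/ns)` (equal scales), so the
  distribution is identical to averaging *n* rendered realizations at a
  sixth of the cost. The 1/n variance scaling is verified by test.
* Foveal geometry — a Gaussian anterior elevation of the ELM (amplitude
  15 µm, σ 0.35 mm; the exact shape is unprinted, a Gaussian bump is
  assumed) locates the fovea, and the sub-band amplitude tapers smoothly to
  zero inside a 0.25 mm foveolar radius, reproducing the reported
  thinning/absence of the sub-band in the foveola. Both amplitudes are
  judgment calls at anatomically plausible values.
* Vessel shadows — whole-A-scan multiplicative attenuation (×0.3) in
  columns near Poisson-placed eccentricities (rate 1.2/eye).

## Cohort design and calibration

The default cohort reproduces the published design: 13 young (22–38 y),
18 middle (42–60 y) and 13 older (62–90 y) eyes, ages uniform within
ranges (only ranges and means are printed). Group-level *measured-ratio*
targets per location are taken from the published group means
(`default_ratio_targets()`), and `calibrate_reflectivity()` inverts the
measurement map by monotone root search on noiseless renders: the measured
peak ratio differs from the intrinsic amplitude fraction because each
band's PSF tail inflates the other's peak (the smaller peak gains
proportionally more) and because the noise floor adds to both peaks.
Reflectivities are intrinsic eye properties, so calibration always runs at
the reference 2.7 µm PSF even when volumes are rendered at a coarser one
(`calibration_psf_fwhm_um`).

Per-eye reflectivities are truncated-normal around the calibrated group
means with `group_sd = 0.12`. This value is a one-time choice: combined
with measurement speckle it yields per-cell measured SDs of ~12–13 points,
inside the published 9–19 range. The designed age trend plus this spread
imply a population Spearman correlation of ratio with age of ≈ 0.5 at the
2 mm temporal location, matching the published r = 0.511.

## Measurement pipeline

1. **Bruch's segmentation** (`segment_brm`): per A-scan, the deepest local
   maximum above 30% of the A-scan maximum after light axial smoothing;
   running median over 5 A-scans; invalid columns filled from neighbours.
   (The study used learned layer segmentation; an intensity rule is valid
   on synthetic data and is explicitly substituted.)
2. **Flattening** (`flatten_to_brm`): per-A-scan shift with linear
   interpolation; integer shifts round-trip exactly, fractional shifts cost
   O(h²) on a ~1.3-pixel-σ band (a few percent of peak — bands are
   deliberately not resampled twice in the pipeline).
3. **Fovea localization** (`locate_fovea`): sub-pixel ELM depth per A-scan
   (parabolic refinement — without it, pixel quantization flattens the
   elevation map), ELM–BrM distance smoothed by a 5 × 5 moving average
   (the smoothing scale is unprinted; a choice), argmax = foveal centre.
4. **Peak measurement** (`measure_eye`): on the horizontal B-scan through
   the fovea, at ±0.5, ±1, ±2 mm (nasal/temporal resolved through
   laterality). The ELM peak is the highest local maximum in a tight
   window around the rough ELM depth; the sub-band is the most prominent
   local maximum 2–10 µm posterior (a window covering the printed IQR with
   margin while excluding the EZ) that is separated from the ELM by a
   hyporeflective gap. Sub-pixel centres and heights use 3-point parabolic
   interpolation (position error ≤ 0.02 µm; height bias ≤ 1.3% at this
   sampling — the bias largely cancels in the ratio and is absorbed by
   calibration). Intensities are never corrected for the noise floor,
   matching the published analysis.
5. **Gap prominence**: in addition to "a local minimum strictly below both
   peaks", the gap must be at least 10% of the ELM peak deep. With ~5%
   per-pixel speckle, bare strict inequality would let noise dips on a
   merged band (6 µm PSF) fabricate a resolved sub-band.
6. **Fallback**: when no distinct peak exists, the sub-band intensity is
   sampled (linear interpolation) at the population-median offset, 4.9 µm
   posterior to the ELM, and flagged.
7. **Shadow rule**: if the target column's mean outer-retina intensity is
   below 0.5 × the B-scan median (the threshold is a choice; the study
   states no criterion), the best column within ±5 A-scans substitutes;
   ties go to the nearer column, then nasally. All candidates shadowed ⇒
   the measurement is unreliable.

## Grading emulation

Human grading is emulated in three layers. The **proxy** calls a location
visible iff a gap-separated peak exists with ratio ≥ 60% on the
representative A-scan and on at least half of the ±5 neighbours (graders
judge B-scan continuity, not single A-scans); the 60% threshold is the
published correspondence between reader visibility and the A-scan ratio.
**Simulated graders** corrupt the proxy's call with configurable
sensitivity/specificity/abstention rates chosen to land pairwise Cohen's κ
in a fair-to-moderate range — configuration, not a claim about any human
panel. **Majority vote** follows the published 2-of-3 rule; when no
binary majority exists the proxy adjudicates (the study used open human
adjudication, which has no analogue here; the replacement rule is explicit
and testable). "Cannot determine" records are resolved before the
contingency tables are built, consistent with the 2 × 3 Cramér's V
arithmetic.

Display preparation for grading mirrors the published protocol: linear
scale, axial stretching (factor 4, chosen so the ELM–sub-band gap spans
≥ 20 display pixels), and an iterative histogram auto-contrast in the style
of the classic ImageJ heuristic (256 bins over the current window; limits
move to the outermost bins exceeding `pixels/5000`; a fixed press count
across eyes operationalizes "visually uniform between subjects"). The
exact heuristic is version-dependent; divisor and press count are exposed.

## Statistics

All tests are implemented from their formulas (and are verified against
independent oracles in the test suite): Kruskal–Wallis with tie
correction, Spearman correlation with the t approximation for p (the
convention of the statistics package used in the study), uncorrected
Pearson χ² — the printed effect sizes reconstruct exactly as
`V = sqrt(χ²/44)` for 2 × 3 tables, implying no continuity correction —
Cramér's V, two-sided Fisher's exact test by hypergeometric enumeration
(2 × 2 only; how larger comparisons were constructed is unprinted), and
Cohen's κ. The pooled per-group mean ratio is the arithmetic mean of the
six per-location group means; the pooled visible percentage divides
visible gradings by eyes × 6 locations (both conventions reproduce the
published pooled numbers from the published per-location rows). Report
rounding follows the published table: means to integers, V to two
decimals.

One published inconsistency is documented rather than reconciled: the
pooled young mean printed in the summary (71.6%) differs from the mean of
the printed young per-location row (72.0%), presumably because it was
computed before rounding; this package computes from full precision.

## What a green test does and does not establish

The simulator emulates band geometry, PSF-limited resolvability, fused
speckle statistics, foveal geometry, age-dependent reflectivity and vessel
shadows. It does **not** model motion artifacts, illumination variation,
curvature before flattening beyond a test displacement, intraretinal
layers, pathology, or the perceptual component of human grading. Absolute
visible fractions in the default cohort are therefore higher than the
published 16.7/47.2/66.7% — the proxy sees every resolvable peak above
threshold, whereas human visibility additionally depends on display
contrast and perceptual salience that are not modelled. The monotone
young < middle < older trend, which the tests assert, is the meaningful
reproduction target.

Compute scaling: cohort-scale runs use a 500 × 25 A-scan strip around the
foveal meridian instead of the full 500 × 500 raster. All six measurement
locations lie on the central B-scan; the strip only narrows the slow-axis
context used for fovea localization. The full raster remains the
`grid_spec()` default.

## Known limitations

* A single-A-scan ratio has σ ≈ 5–6 percentage points under the default
  speckle; per-cell (group × location) means over 13–18 eyes consequently
  carry SE ≈ 1.5 points, so cell-level recovery of design targets is
  accurate to ~±3 points, not better. The pipeline's own bias, measured
  noiselessly, is ≤ 1.3 points.
* The distinctness ("visibility") of the sub-band is driven entirely by
  its amplitude and the PSF; no separate diffuseness axis (e.g. band
  widening with age) is modelled.
* Fisher's exact test supports 2 × 2 tables only.
* The CLI's `grade` subcommand, operating on a measurement CSV without
  B-scan context, uses the single-A-scan proxy (no neighbourhood vote).
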