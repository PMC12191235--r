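---
title: "Methods: single-cell fate calling and radiation-assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell fate calling and radiation-assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radassay)
```

radassay quantifies how small extracellular vesicles (sEVs) shed by
radioresistant glioma cells protect radiosensitive H3K27M-mutant diffuse
midline glioma cells from radiation. Bulk viability assays are confounded by
the sEVs themselves, so the central readout is single-cell: a genetically
encoded death indicator (GEDI) combining a calcium sensor (GC150, green)
with a constitutive marker (mApple, red). Apoptotic commitment floods the
cell with calcium, the green/red ratio rises irreversibly, and shortly
afterwards the dead cell detaches and disappears from the field of view.
This vignette describes the models, parameters and numerical choices behind
each stage, and what the synthetic benchmark does and does not demonstrate.

## The GEDI fate model

For cell $i$ at scheduled imaging time $t$ (hours post-irradiation), the
measured per-cell mean intensities give the ratio

$$R_i(t) = \frac{\bar G_i(t)}{\bar R_i(t)},$$

computed only where the red denominator exceeds a floor; an unmeasurable
cell yields `NA`, never a zero (a zero would mimic a healthy cell).
$R$ is invariant to a common gain on both channels and linear in the
green-channel gain — both asserted in the test suite.

A cell is called dead at the earliest of:

* **ratio crossing** — first scheduled timepoint with $R > \theta$;
* **disappearance** — first scheduled timepoint at which a
  previously-present cell is absent from the field of view.

Cells still present with $R \le \theta$ at the last timepoint are censored
there. Both causes are recorded, so either convention (crossing+disappearance
or disappearance only) can be reproduced via the `rule` argument of
`call_fates()`. Cells that appear only after the baseline frame (drift-in,
division) were not at risk at $t = 0$ and are excluded rather than treated
as births.

**Threshold.** The default is the fixed rule $\theta = 1$. When a
calibration experiment is available (ratios at baseline versus 24 h after a
lethal 25 Gy dose), `calibrate_threshold()` finds the cut minimising total
misclassification between the two empirical distributions by exhaustive
scan over the midpoints of consecutive sorted values, breaking ties at the
midpoint of the tied range. If no cut misclassifies fewer than half the
cells the distributions are inseparable and calibration fails loudly rather
than returning a meaningless $\theta$.

**Survival analysis.** `km_curve()` is the product-limit estimator
$S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ with censored cells leaving the
risk set after their censoring time. `logrank()` uses the classical
observed-minus-expected statistic with hypergeometric variance, ties pooled
at identical times; with $k$ groups the statistic is the quadratic form over
$k-1$ groups. Both are validated against independent oracles (hand
product-limit computation, `survival::survfit`/`survdiff`, and a label
permutation oracle).

*Small-sample p-values.* With a handful of cells per arm and only four
possible event times, the $\chi^2_1$ reference distribution is a poor
approximation: we measured discrepancies of 0.02–0.09 between the
asymptotic p and the exact permutation p at $n = 6$/group. `logrank()`
therefore computes the p-value by complete enumeration of the group-label
assignments (the conditional permutation null of the statistic) whenever a
two-group cohort admits at most 5,000 assignments, and falls back to the
asymptotic $\chi^2$ otherwise; `p.method` records which was used. The
statistic itself is always the classical one.

**Tracking.** Fields are sparse (2,500 cells/well seeding), so
`track_cells()` uses greedy nearest-centroid matching between consecutive
scheduled timepoints, taking candidate pairs in order of increasing
distance and refusing matches beyond `max_displacement_px` (default 24 px,
about four cell radii). No global assignment is attempted; at these
densities greedy matching is adequate and an order of magnitude simpler.
Interval-censored deaths are assigned to the right endpoint (the first
timepoint at which the cell is absent), since the product-limit estimator
needs a time.

## Image preprocessing and segmentation

The segmentation chain mirrors the original imager workflow: background
subtraction, approximate PSF sharpening, thresholding, connected-component
labeling, and per-mask intensity measurement on the red-channel masks.

* `rolling_ball()` estimates background by grayscale morphological opening
  (erosion then dilation) with a square window of half-width `radius_px`,
  implemented as separable running minima/maxima with $O(\log r)$
  whole-matrix shifts; the estimate is subtracted and the result clipped at
  zero. A constant image maps to zero; a small bright spot survives with
  its amplitude intact. Window borders use truncated windows, so the
  background is least constrained within one radius of the image edge — a
  shared limitation of rolling-ball estimators.
* `sharpen_psf()` is Gaussian unsharp masking,
  $I + s\,(I - G_\sigma * I)$, clipped at zero. No point-spread function is
  published for the imaging, and the step only feeds thresholding, so true
  Richardson–Lucy deconvolution would add cost and fragility for no
  downstream benefit. `strength = 0` is exactly the identity.
* `threshold_mask()` offers a manual threshold (the original analyses used
  manually chosen values, which are irreproducible) and Otsu's
  between-class-variance criterion on a 256-bin histogram as the
  reproducible default. When the histogram valley between modes is empty
  the criterion plateaus; the cut is placed at the middle of the tied
  range, which is what an exhaustive scan over sample values yields. A
  constant image raises a degenerate-histogram error. In automatic mode an
  implausibly large foreground (more than `max_foreground_fraction` of the
  field, default 25%) is treated as an empty field: a blank frame has no
  bimodal histogram and Otsu would otherwise split the noise.
* `label_objects()` labels 8-connected components (4-connected labeling
  plus a union-find merge of diagonal touches) and discards components
  below `min_area_px` (default 20 px; unspecified in the original work and
  configurable), renumbering labels consecutively.

Mean red/green intensities per object are measured on the
background-subtracted channels, so the GEDI ratio reflects cell signal
rather than camera offset. Nuclear (DAPI) segmentation reuses the same
chain on the blue channel and flags objects with area above the field's
mean + 3 SD as candidate merged nuclei; no watershed splitting is attempted
(a documented non-goal), so touching objects merge and are only flagged.

All coordinates are 1-based (row, col) matrix indices, pixel-centred,
applied uniformly across the generator, segmentation and tracking.

## Foci counting

DNA-damage foci (53BP1trunc-mApple puncta in live cells; gamma-H2AX
immunofluorescence in fixed cells) are counted per compartment — red-cell
masks for 53BP1, nuclear masks for gamma-H2AX; the operator chain is
otherwise identical, which the tests assert by running both paths on the
same stack.

The acceptance rule is the study's "order of magnitude above background":
a punctum is a connected component of pixels at or above
`contrast_factor` (default 10) times the *per-cell* background, the median
of in-mask intensities after excluding the brightest 5% (reporter
expression varies cell to cell, so a global background would be wrong; the
trimming keeps a handful of bright puncta from inflating the estimate).
Area bounds of 2–50 px reject hot pixels and saturated patches. Because
the rule is a ratio, counts are invariant to global gain. Lowering the
contrast factor can only grow candidate regions, so counts are
non-decreasing — up to the resolution limit: two puncta whose candidate
regions touch merge into one component. The package does not split merged
puncta; the generator's default minimum focus separation keeps puncta
resolvable at the default contrast factor.

Group comparisons use one-way ANOVA (single timepoint) or two-way ANOVA
(group × timepoint) with Tukey HSD pairwise contrasts, via `aov()` and
`TukeyHSD()`. One boundary case is defined explicitly: when the
between-group sum of squares is exactly zero the classical F is 0/0; the
package reports F = 0 with p = 1, since no between-group variation is no
evidence of a difference.

## Plate-level assays

* **Viability**: $100 (L_T - L_B) / (L_0 - L_B)$ with replicate wells
  averaged first; blank $L_B$ from media-only wells, $L_0$ from the
  unirradiated control. Invariant to affine luminometer rescaling. The
  assay fails loudly when the 0 Gy control does not exceed the blank.
* **Colonies**: the same preprocessing chain with a colony-scale minimum
  area; touching colonies are counted as one object and flagged when the
  pixel footprint fills less than 75% of the circumscribed circle
  (a merged pair of discs fills about half).
* **Flow cytometry**: a rectangular FSC/SSC gate removes debris (defaults
  placed between the generator's debris cluster, at roughly 10% of cell
  forward scatter, and the cell population); positivity is fluorescence
  above the 99th percentile of the matched unstained reference (the
  published gate is only "above the unstained cell gate"; the percentile
  is configurable). MFI is reported as arithmetic mean to match the usual
  "mean fluorescence intensity", with a geometric option; both
  all-singlets and positives-only MFI are emitted because which was used
  is unstated in most reports.
* **sEV dosing**: particles per cell = concentration × volume / cells,
  reproducing the study's 2,500 / 5,000 / 15,000 particles-per-cell dose
  levels from particle totals and cell counts.
* **Mitochondrial stress test**: with the rotenone/antimycin floor
  $N$ (phase mean), basal respiration is the last basal measurement minus
  $N$ (the vendor-convention last pre-injection point; the source is
  silent), maximal respiration the FCCP-phase peak minus $N$, spare
  capacity their difference, also expressed as percent of basal. A trace
  whose basal does not exceed the floor is invalid.

## The synthetic benchmark: what it emulates, and what it does not

`sim_timelapse()` renders cells as isotropic Gaussian blobs (downstream
operators only need masks and mean intensities, so shape realism buys
nothing), with per-cell lognormal red amplitude, green = red × ratio, a
step ratio transition at death (an abrupt shift matches the biosensor's
irreversible calcium influx and keeps truth unambiguous; a ramp-duration
parameter exists, defaulting to 0), exponential death hazards (no hazard
form is published; a Weibull shape parameter is exposed), post-death
detachment after a delay, Gaussian read noise with optional Poisson shot
noise, and small centroid jitter. Defaults encode the study conditions:
schedule 0/6/12/18 h; hazards control 0.12, low 0.08, medium 0.06, high
0.04 events/h (a 3:1 control:high ratio); $r_\text{live} = 0.5$,
$r_\text{dead} = 1.8$ (dead-cell ratios near the reported scale of ~1.8);
detachment delay 6 h with probability 0.9; red amplitude lognormal
(meanlog log 2000, sdlog 0.25) over background 100 with noise SD 10
(spot SNR well above 10); cell radius 6 ± 1 px in a 512×512 field
(768×768 at 200 cells to keep fields sparse). No published
magnification-to-pixel scale exists for these acquisitions, so pixel
geometry is arbitrary and documented rather than physical.

`sim_foci_stack()` renders soft-edged nuclei (radius 14 px in a 640×640
field) carrying Poisson($\lambda$) puncta, each a PSF-blurred spot
(σ = 1.2 px) whose peak is 20× the cell's diffuse level, with a 4 px
minimum separation — discrete puncta on a diffuse background, the geometry
real gamma-H2AX images show. A generator whose foci would carpet most of
the nuclear area both looks nothing like data and breaks any
trimmed-median background estimate. Foci at or below cell background
(intensity factor ≤ 1) are refused: they are undetectable under the
order-of-magnitude criterion by construction.

`sim_colony_image()`, `sim_flow_events()` and `sim_ocr_trace()` provide
disk colonies (disjoint by default, optional overlap with truth flags),
log-normal unstained/stained flow populations (shift factor 100, halved
per division generation, 5% debris) and four-phase OCR traces
(basal/oligomycin/FCCP plateau/floor = 100/40/180/20 with noise SD 3).
`sim_fate_tracks()` is the track-level counterpart of the time-lapse
generator for studying the survival stages without rendering pixels.

Identical parameters and seed reproduce every output bit for bit; each
generator returns machine-readable ground truth (positions, death and
detachment times, per-cell focus counts, event labels, noiseless OCR
metrics), and truth row counts always equal the requested object counts.

**What passing does not show.** The benchmark has no optics beyond a
Gaussian PSF, no photobleaching, no cell migration or division, no
overlapping cells, no autofluorescence or debris in images, and no flow
compensation/spillover. Segmentation recall ≥ 95% and ≥ 95% fate-call
agreement on these fields demonstrate that the operator chain is correct
and well-calibrated, not that it would achieve those numbers on crowded,
drifting, photobleaching real acquisitions; on real data the manual
thresholds, displacement bound and contrast factor are the knobs to
revisit.

## Problem sizes and runtime

The test suite exercises the full image pipeline at 200 cells per 768×768
field across four timepoints, foci detection at 100 nuclei with λ = 5, and
statistical checks at up to 1,000 simulated cells per arm with a
100,000-resample permutation oracle; the whole suite runs in a few minutes
on one core. The headline survival comparison (two arms of 200 cells,
hazards 0.12 vs 0.04 events/h) takes under a second at the track level.

## Known limitations

* No watershed splitting: touching cells/nuclei/colonies are merged and
  flagged, never split.
* Greedy tracking can mismatch when displacement approaches the
  inter-cell spacing; the default bound assumes sparse fields.
* Log-rank p-values are exact only for tiny two-group cohorts; pairwise
  dose comparisons use the asymptotic statistic.
* Rolling-ball background is unreliable within one window radius of the
  image border (as with any opening-based estimator).
* Flow gating assumes the synthetic-geometry FSC/SSC scales unless the
  gate bounds are configured; no FCS binary parsing (CSV exports only).
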