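# radassay

Quantification pipeline for radiation-response experiments in
patient-derived H3K27M diffuse midline glioma cultures, built around
single-cell death calling with the GEDI biosensor (a genetically encoded
death indicator: calcium-sensitive GC150 normalized to constitutive
mApple). Bulk viability assays are confounded when cells are treated with
small extracellular vesicles (sEVs), so radioprotection is read out cell by
cell: each cell's green/red ratio

    R(t) = mean GC150 / mean mApple

rises irreversibly at apoptotic commitment; cells with `R > θ` (θ ≈ 1,
calibrated from a lethal 25 Gy exposure) are called apoptotic, and
disappearance from the field of view counts as death as well. Per-cell
fates feed a Kaplan–Meier product-limit estimator and log-rank tests
between treatment arms (with exact permutation p-values for tiny cohorts).

Around that core the package implements the study's other bespoke
quantifications, each exercisable on synthetic data with ground truth:

* **imaging** — rolling-ball background subtraction, unsharp PSF
  sharpening, manual/Otsu thresholding, 8-connected labeling, red-channel
  cell masks and DAPI nuclear masks with per-mask intensity measurement,
  greedy nearest-centroid tracking;
* **DNA-damage foci** — 53BP1 / gamma-H2AX puncta per cell under the
  "order of magnitude above per-cell background" rule, timecourse
  summaries, ANOVA + Tukey group comparisons;
* **plate assays** — blank/0 Gy viability normalization, colony counting,
  flow-cytometry debris and positivity gating against an unstained
  reference, sEV particles-per-cell dosing arithmetic, and mitochondrial
  stress-test metrics (basal/maximal/spare respiratory capacity);
* **synthetic data** — generators for GEDI time-lapse stacks, foci fields,
  colony plates, flow event tables and OCR traces, all seeded,
  deterministic and paired with machine-readable truth.

Everything tabular flows through tibbles, so results chain with the pipe;
fitted test objects support `tidy()`/`glance()`, and each result type has a
plot function (`autoplot()` for KM curves, `plot_gedi_tracks()`,
`plot_foci_timecourse()`, `plot_flow_hist()`, `plot_ocr_trace()`).

## Worked example

Two synthetic arms of 200 cells with exponential death hazards 0.12
(control) vs 0.04 events/h (high-dose sEV), observed at 0/6/12/18 h
post-irradiation; fates called at θ = 1, then KM + log-rank:

```r
library(radassay)

sim   <- sim_fate_tracks(200, c(control = 0.12, high = 0.04),
                         detach_prob = 0, seed = 1)
fates <- call_fates(sim$tracks, theta = 1)
km    <- km_curve(fates)
km[km$time == 18, ]
#> # A tibble: 2 × 6
#>   group    time n_risk n_event n_censor survival
#>   <chr>   <dbl>  <int>   <int>    <int>    <dbl>
#> 1 control    18     37      20       17    0.085
#> 2 high       18    123      19      104    0.52

logrank(fates)
#> Log-rank test: chi-square = 99.74 on 1 df, p = 1.73e-23 (n = 400, events = 279)
#> # A tibble: 2 × 3
#>   group   observed expected
#>   <chr>      <dbl>    <dbl>
#> 1 control      183     118.
#> 2 high          96     161.
```

Survival at 18 h is 8.5% in the control arm versus 52% under high-dose
sEVs — the dose-dependent radioprotection the single-cell assay is designed
to resolve — and the log-rank test rejects equal hazards decisively
(p ≪ 0.001). `autoplot(km)` draws the step curves.

The supporting assays follow the same data-frame-first style:

```r
calibrate_threshold(rnorm(500, 0.6, 0.2), rnorm(500, 1.4, 0.2))
#> <gedi_calibration> theta = 0.9692 (misclassification 1.80%, n = 500 + 500)

seahorse_metrics(sim_ocr_trace(100, 40, 180, 20, noise_sigma = 0)$trace)
#> # A tibble: 1 × 5
#>   nonmito basal_resp maximal_resp spare_abs spare_pct
#> 1      20         80          160        80       100

sev_dose(1e8, 1, 2e4)   # 5000 particles per cell
```

A full image-level walkthrough (simulate → write TIFF → segment → track →
fates) is in the methods vignette (`vignettes/radassay-methods.Rmd`); a thin
command-line wrapper with `simulate` / `segment` / `gedi` / `foci` /
`viability` / `colonies` / `flow` / `ocr` subcommands lives at
`inst/scripts/radassay-cli.R`.

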