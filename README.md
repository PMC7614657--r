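# rtqibc

Retrospective time-lapse synchronized quantitative image-based cytometry
(RT-QIBC) in R.

## The problem

Quantitative image-based cytometry (QIBC) measures thousands of fixed,
stained single cells — immunofluorescence, EdU incorporation, DNA content —
but a fixed snapshot has no time axis: an asynchronous population mixes cells
at every cell-cycle position. RT-QIBC restores the time axis by filming the
same cells live before fixation. Nuclei expressing cell-cycle reporters
(an H2B fusion for segmentation and tracking, a CRL4^Cdt2^-degron reporter
whose degradation marks S-phase entry, an APC/C^Cdh1^ reporter whose
stabilization marks the G1/S commitment point, and PCNA whose puncta mark
active replication) are segmented, tracked through mitosis, and annotated
with per-cell event times. The plate is fixed immediately after the movie,
stained and re-imaged; the fixed image is registered to the last live frame
by cross-correlation, each fixed cell is matched to its own live track, and
every fixed-cell measurement is re-indexed as *time since that cell's own
event* — e.g. endogenous CDT1 immunofluorescence as a function of minutes
since S-phase entry, at a temporal resolution limited only by the imaging
interval.

The package implements the full pipeline — flat-field and bleedthrough
correction, Laplacian-of-Gaussian nuclear segmentation with curvature-based
splitting of touching nuclei, nearest-neighbour tracking with an
intensity-conservation invariant and mitosis detection, drop/rise/dual-
threshold event detectors, live-to-fixed registration and matching — plus
the downstream statistics: percentile gating, Hill dose–response fitting of
single-cell EdU inhibition, robust zero-intercept fits, bootstrap percentile
intervals, and Pearson colocalization with a 4-direction pixel-shift
randomization null. A seeded synthetic-microscopy generator provides
ground-truthed movies, fixed snapshots and dose–response tables, so every
stage is benchmarked against known truth.

## The model at the core

Single-cell EdU incorporation versus the nuclear level of a non-degradable
CDT1 fragment (ND-CDT1, `x`) follows a Hill dose–response

```
EdU(x) = EdU_max − (EdU_max − EdU_min) / (1 + (IC50 / x)^n)
```

`EdU_max` is fixed from cells not expressing ND-CDT1; `EdU_min`, `IC50` and
the Hill coefficient `n` are fitted by Levenberg–Marquardt least squares,
initialized at the 5th percentile of EdU, the median ND-CDT1 level, and 1.
`fit_hill()` returns a classed model object with `print`, `summary`, `coef`,
`predict`, `plot` and `residuals` methods; `fold_inhibition()` is
`EdU_max / EdU_min`, and `stratified_dose_response()` refits the curve in
equal-count strata of a second marker (e.g. geminin) and regresses the
per-stratum IC50 on the stratum median.

## Worked example

```r
library(rtqibc)

# 1. Hill fit on a synthetic single-cell dose-response table
hp <- hill_params(edu_max = 22, edu_min = 1, ic50 = 10.2, n_hill = 4.2)
d  <- sample_dose_response(hp, n = 12039, noise_cv = 0.3,
                           expression_range = c(0.5, 40), seed = 1,
                           n_negative = 2000)
fit <- fit_hill(d$ndcdt1, d$edu)
fit
#> Hill dose-response fit (Levenberg-Marquardt)
#>   EdU_max 21.97 (fixed)  EdU_min 1.035  IC50 10.21  n 4.289
#>   12039 cells, residual SS 3.313e+05, max inhibition 21.2-fold

# 2. A full synthetic RT-QIBC site: simulate, render, segment, track,
#    annotate, register, match, and emit event-aligned records
cfg <- sim_config(seed = 11)
res <- run_rtqibc_site(cfg)
head(res$records[, c("track_id", "time_since_s_entry_min",
                     "s_entry_source", "fixed_CDT1IF_total",
                     "fixed_EDU_total")])
```

The fitted parameters land on the generating values (IC50 10.21 vs 10.2
a.u., Hill coefficient 4.29 vs 4.2, 21.2-fold vs 22-fold maximal inhibition
at this noise level and sample size). In the records table, each fixed cell carries its measured
immunofluorescence and EdU totals together with the minutes elapsed since
its own S-phase entry, reconstructed from its live reporter trace; plotting
`fixed_CDT1IF_total` against `time_since_s_entry_min` reproduces the
programmed exponential decay of endogenous CDT1 after S entry.

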