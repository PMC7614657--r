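---
title: "RT-QIBC: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-QIBC: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rtqibc)
```

This vignette explains the science implemented by `rtqibc`: what each stage
of the pipeline assumes, which parameters matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and where genuinely open design choices were resolved.

## What RT-QIBC measures

A fixed-cell stain is a single time point. Retrospective time-lapse
synchronized QIBC gives every fixed cell its own clock: the cells are filmed
live with cell-cycle reporters before fixation, each fixed cell is matched
back to its live track, and its stain measurements are re-indexed as time
since a cell-cycle event detected on that track. The reporters carry the
event information:

* **H2B fusion** — constitutive chromatin label; used for segmentation and
  as the tracking invariant (total nuclear H2B is conserved between frames
  and split between daughters at mitosis).
* **CRL4^Cdt2^-degron reporter** — accumulates through G1 and is rapidly
  degraded when PCNA loads at fired origins; the degradation onset is an
  explicit S-phase-entry mark.
* **APC/C^Cdh1^ reporter** — held near zero through G1 by APC/C^Cdh1^ and
  stabilized at its inactivation near the G1/S commitment point.
* **PCNA puncta** — replication foci; their area jumps from ~0 at S entry.

## The synthetic-data generator

Real microscopy is replaced by a seeded generator whose defaults define the
benchmark conditions used throughout the tests.

**Cell cycle.** Phase durations are lognormal (positive and right-skewed
like measured cycle times) with medians G1 540 min, S 540 min, G2/M 300 min
and CVs 0.25/0.15/0.20 — an ~23 h epithelial-like cycle. Founders start at a
uniformly random position in their cycle; daughters inherit expression
levels, and total H2B splits ~48/52 at division. The movie default is 120
frames at 12 min (24 h) with 50 initial cells on a 640×640 px field at
0.65 µm/px.

**Reporter kinetics.** The source material states only that the reporters
"accumulate" and are "degraded"; the functional forms here are a modelling
choice, flagged in the configuration: the CRL4 reporter rises linearly from
anaphase to S entry and decays exponentially afterwards (half-time 8 min);
endogenous-CDT1 immunofluorescence decays exponentially from S entry with a
9-min half-time, which puts it below the 10% "fully degraded" gate ~30 min
after S entry; the APC/C reporter and the geminin-like stain ramp linearly
from APC/C inactivation, which leads S entry by a lognormal ~30 min; PCNA
foci area ramps to a 120 px plateau over the first 30 min of S phase. EdU
equals the Hill-model response at the cell's ND-CDT1 level for cells in S at
fixation (the few-minute pulse average is absorbed into the multiplicative
noise), and ~0 otherwise.

**Motion.** Cells take isotropic Gaussian steps (default 1.5 px/frame) and
are then relaxed apart wherever two nuclei come closer than 0.7× their
summed radii. The exclusion term deserves a note: a pure free random walk
lets nuclei interpenetrate almost completely for tens of minutes, a regime
that no segmentation can resolve even in principle and that interphase
monolayers do not exhibit. The relaxation keeps nuclei touching but not
concentric, which is both more realistic and what makes the stated tracking
and matching benchmarks meaningful. Density is still bounded at
configuration time (packing fraction of exclusion discs ≤ 0.55).

**Rendering and camera.** Nuclei are isotropic Gaussian blobs truncated at
2.5σ (= the nuclear radius), scaled so the pixel sum equals the cell's
total intensity exactly — intensity conservation is by construction, which
is what the tracking invariant assumes. The camera model applies
`offset + profile × (signal + bleedthrough) + noise` with a smooth Gaussian
illumination profile, Gaussian read noise plus a Poisson-like variance term,
and per-channel-pair linear bleedthrough; with noise disabled the mapping is
exactly inverted by the correction module, and the tests assert that.

**What the generator does not emulate** — photobleaching, focus drift, 3D
optics, pre-extraction physics, debris, segmentation-hostile textures
(nucleoli, apoptotic bodies), or drug treatments beyond parameter changes.
Passing the benchmarks therefore demonstrates the pipeline's internal
consistency and its behaviour under the stated noise model, not performance
on arbitrary real data.

## Image correction

The illumination profile is estimated from background autofluorescence in
areas without cells: per-pixel median across ≥ 10 sites (masked pixels
excluded), gap filling, low-pass smoothing at field scale (Gaussian,
σ = 5% of the image width), normalization to mean 1. Two numerical details
matter. The per-pixel summary is a median (the source does not state mean
vs median; the median is insensitive to residual cell pixels). And the
smoothing pads the field by *linear extrapolation* rather than mirroring:
mirror padding kinks the boundary gradient of a smooth profile and biases
the corners by several percent, while gradient-preserving padding keeps the
estimate within 1% of truth everywhere.

## Segmentation

Live H2B images go through a multiscale Laplacian-of-Gaussian detector
(scale-normalized, 3 log-spaced scales across the configured diameter
range). Each response maximum above threshold seeds an object; extent is a
local threshold at 8% of the seed's peak above the local background, and
contested pixels go to the nearest seed so that pixel assignment at touching
nuclei is stable from frame to frame — an instability here masquerades as
signal non-conservation and breaks tracks. Duplicate-seed suppression uses a
deliberately small margin (0.35× the minimum diameter) so nearly-touching
nuclei keep separate seeds. An optional region-based active-contour
refinement (piecewise-constant energy, 50 iterations) is available for
low-contrast movies and off by default.

Fixed DNA-stain images are thresholded by histogram curvature: on
log-binned intensities the background peak's log-counts form a parabola of
constant curvature, and the threshold is taken at the first prominent
positive-curvature peak after the mode — the foot of the shoulder, where it
meets the inter-class valley. Log-domain binning makes the threshold
scale-covariant (doubling intensities doubles it exactly).

Objects larger than the median object size are checked for splitting:
concavity points are local maxima of negative perimeter curvature (tangent
angle differences on a smoothed closed contour, σ = 2 contour samples,
threshold −0.15 rad/px), and the chosen pair maximizes perimeter distance
over Euclidean distance. Splitting assigns pixels to the two sides of the
chord — no pixel is removed, so the foreground pixel count is invariant.
If a previous cut consumed one partner of a waist, a lone concavity is cut
to the nearest contour point at least a quarter perimeter away, subject to
the same ratio gate; this is what lets three-lobed clumps resolve
recursively.

## Quantification

Backgrounds are the 25th percentile of pixels outside the nuclear mask
dilated by 7.8 µm (15.6 µm for signals with a cytoplasmic component).
Per-cell statistics are background-subtracted means, medians and totals;
cytoplasmic rings span 0.65–3.25 µm outside the nuclear edge, excluding any
other nucleus and its inner dilation (the source is silent on occlusion; the
exclusion rule avoids neighbour contamination), and the ring/nuclear median
ratio is the CDK-activity readout. PCNA puncta area is the pixel count
above a chosen threshold after a morphological top-hat (radius 2 px for
wide-field, 3 px for confocal). One practical note: the 25th-percentile
background estimator under-subtracts in the presence of noise, leaving a
small positive floor on faint cells; downstream analyses that need a true
zero subtract a measured baseline (see the decay fit below), which is also
how the stain-normalization operation is meant to be used.

## Tracking

Frames are linked by mutual nearest neighbours within a gate (3× the motion
σ, floor 10 px). Total nuclear H2B is used as a conserved quantity: links
whose signal changes by more than 25% are not accepted blindly but reviewed.
A current object matching the summed signal of a flagged link's predecessor
plus a lost neighbour is a segmentation merge: the observation is split at
the carried-forward centroids, every extensive quantity (signal totals,
areas) apportioned at the pre-merge ratio, and both tracks stay alive for as
long as the merge lasts. When the merged object separates again the two
fragments are re-assigned by signal similarity — the apportionment preserved
each track's total, so the cells' different H2B levels identify them. A pair
still merged at movie end after ≥ 3 frames ends its weaker member as lost.
Mitoses are one track ending with two new tracks within 4 nuclear radii
whose summed signal is within 30% of the parent's; a "division" whose
daughter pair re-merges within 3 frames is reclassified as a spurious split
and stitched back. Tracks never close gaps across missing frames.

## Event annotation

All detectors use a fixed look-ahead window (3 frames) so that detection
latency is independent of how long before fixation the event occurred —
otherwise cells fixed soon after their event would be systematically harder
to annotate than cells fixed long after, biasing every event-aligned curve.

* **Degradation onset** (CRL4 reporter, CDT1 fusions): earliest frame where
  the window slope of the running-max-normalized trace is ≤ −0.03/frame,
  the local curvature marks a peak/corner (≥ 0.01), the drop across the
  window is ≥ 10% of the cell's overall expression, and the preceding frame
  sits at ≥ 75% of the onset level (degradation starts from a plateau; a
  one-frame spike does not qualify). Traces whose maximum never reaches a
  configurable absolute expression floor are not annotatable — the drop
  criteria are scale-free and would otherwise fire on pure noise.
* **Accumulation onset** (APC/C reporter): earliest frame with forward slope
  ≥ +0.02/frame from a level ≤ 0.1 that begins rising immediately and
  climbs to 0.25 without dipping back below 0.1 (the persistence clause
  rejects transient blips).
* **S entry from PCNA foci** (dual threshold): first frame above 50 px that
  exceeds the previous 4 frames marks established S phase; S entry is the
  last frame before it below 3 px. The high threshold is crossed well after
  entry by design; the low threshold recovers the true entry frame.

The slope/curvature/level defaults were calibrated once on the synthetic
benchmark and exposed in the configuration; they play the role of the
empirically-determined-and-checked-by-eye thresholds used in manual
practice.

## Registration, matching, records

Fixed images are registered to the last live frame by the peak of the
normalized circular cross-correlation, after bringing both to the fixed
scale (bicubic upsampling of the live image, or mean-value binning of the
fixed one; both strategies are implemented and agree within a pixel). Fixed
cells are assigned greedily, in ascending distance, to at most one live cell
within one nuclear radius — greediness prevents two fixed cells mapping to
one track after a late division. Acquisition-time offsets follow the site's
0-based position in the acquisition cycle divided by the number of
positions, times the frame interval. Event-aligned times are
`(movie end + site offset) − event time`, and records keep their
measurements with missing times when the event was not annotated.

## Dose–response statistics

The Hill fit minimizes unweighted squared residuals by Levenberg–Marquardt
with the stated initialization (EdU_min at the 5th EdU percentile, IC50 at
the median ND-CDT1, n = 1) and a small restart grid (IC50 ×{0.3, 1, 3},
n ×{0.5, 1, 2}) on non-convergence. The EdU ceiling is fixed from
ND-CDT1-negative cells; in the simulations 2000 negative cells accompany
each table, enough that the ceiling's sampling error (< 0.5%) is negligible
against the 5% recovery tolerances. Zero-noise data are recovered to at
least four significant digits, and on noisy data the returned objective is
checked in the tests against a brute-force grid oracle with the floor
parameter profiled in closed form. Uninhibited data (no EdU decrease across
the dose range) are rejected as degenerate rather than fitted. No
multiple-testing correction is applied anywhere; p-values are reported raw.

The end-to-end decay benchmark reconstructs the programmed endogenous-CDT1
half-time from the records: fixed-cell CDT1 totals of early-S cells are
normalized as `(y − floor) / (G1 − floor)`, where G1 is the median of
live-identified G1 cells (daughters before APC/C inactivation) and the
floor is the median of deep-S cells (> 90 min after entry), giving a true
zero; times are shifted by half a frame interval to centre the quantization
of the dual-threshold entry frame; and the half-time comes from the robust
zero-intercept fit of log2 ratios against time. With 4 sites × 50 cells the
fit uses on the order of ten cells and lands within a few percent of the
programmed 9 min.

## Problem sizes

The default benchmark sizes — one 640² site for segmentation,
a 40-founder field for tracking, a 4-site × 50-cell plate at 120 frames for
the end-to-end run, 20 seeds × 4,500–12,000 cells for the dose–response
recovery — were chosen as the smallest populations at which the acceptance
tolerances are comfortably resolvable; all are package choices encoded in
the test suite.

## Known limitations

* Identity through a long segmentation merge rests on the H2B-total
  difference between the two cells; sibling daughters with near-equal
  H2B can still swap.
* Events earlier than the movie start, or closer to fixation than the
  look-ahead window, are structurally unannotatable; records keep their
  measurements with missing times.
* The curvature-based splitter assumes waist-like concavities; it will not
  separate nearly concentric overlaps.
* The dual-threshold S-entry detector requires a foci trace that starts
  below the low threshold within the track; tracks born mid-S fall back to
  the CRL4 drop detector, which needs the pre-S peak to be in view.
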