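---
title: "Quantifying live-tissue calcium responses and the setpoint curve"
author: "calsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying live-tissue calcium responses and the setpoint curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Parathyroid tumors lose the ability to suppress parathyroid hormone
(PTH) when extracellular calcium rises, and the defect is heterogeneous:
within a single tumor, cells show distinct kinetic patterns of
calcium-induced intracellular flux. The assay this package quantifies
images viable 300-µm tissue slices loaded with the calcium indicator
Fluo-4-AM: a confocal time series (by default 132 frames at 5-s
intervals over a 606.1-µm field, 8-bit) opens with a 30-s six-frame
baseline, extracellular calcium is added, and the record closes with an
ionomycin challenge that should drive flux in every viable, loaded cell.
The scientific outputs are (i) per-cell kinetic waveform classes, (ii)
the proportion of *maximal responders* per calcium dose, and (iii) the
four-parameter logistic (4PL) "setpoint" curve in log calcium whose
midpoint is the tumor's calcium EC50.

## The synthetic scene generator

No imaging data for this assay are deposited anywhere, so the generator
is a first-class module, not a test fixture. It emulates:

* the acquisition geometry and timing above (`AcquisitionMeta`);
* a cell population of soft-edged disks (radius 5.5 ± 0.5 µm,
  i.e. ~11-µm cells) placed by rejection sampling with a 6-µm minimum
  gap. The gap, together with a compact footprint support (logistic
  edge of 0.35-µm softness truncated at weight 0.1), guarantees that
  footprints of distinct cells never own adjacent pixels on either the
  512- or 256-pixel grid, so connected-component ground truth is
  unambiguous. Real tumor tissue is confluent; separability is a
  deliberate idealization that makes exact label-level scoring possible;
* latent kinetic classes per viable cell: **maximal** (saturating rise,
  τ = 5 s, to a 6-fold plateau), **transient** (same rise, then
  exponential decay, τ = 60 s), **gradual** (90-s onset delay, slow
  rise τ = 120 s to 5-fold), **nonresponder** (flat), plus a 5 %
  **nonviable** fraction that ignores both calcium and ionomycin and is
  bright in the viability (propidium-iodide-like) channel. All viable
  cells mount a fast 6-fold ionomycin spike. The assay literature shows
  these waveform shapes without equations; the parametric forms
  here are the package's own choice and are exposed in
  `defaultKinetics()`;
* a dose-dependent mixture: P(maximal | dose) follows a 4PL (default
  bottom 0, top 0.8, EC50 3.2 mM, Hill 4 — the configured "true"
  setpoint), with the residual mass split 25/25/50 over
  transient/gradual/nonresponder;
* noise: additive Gaussian read noise (sd 1.5) plus a signal-
  proportional variance component (scale 0.02), applied per pixel, then
  rounding and 8-bit clipping (clipping is flagged on the movie).
  Amplitudes (background 10, per-cell baseline 25 ± 2.5) are chosen so
  the full response range, including the ionomycin spike, stays inside
  8 bits;
* paired post-fixation fields: nuclei re-rendered under a configurable
  rigid transform and a PTH channel painted per latent class, for
  known-truth registration and colocalization tests;
* timed circulating-PTH series,
  `plateau + (p0 − plateau)·2^(−t/half-life) + noise`.

What the generator does **not** emulate: optical point-spread functions,
z-stacks (the analysis consumes z-projections), photobleaching,
cell movement, and confluent/overlapping tissue texture. Green tests
therefore demonstrate correctness of the *quantitation*, not robustness
to every property of real micrographs.

The eight assayed doses are 0.5, 0.75, 1.0, 1.25, 2.0, 3.0, 5.0 and
10.0 mM; 1.25 mM is the normocalcemic reference.

## Detection and traces

Nuclei are counted by scale-normalized Laplacian-of-Gaussian blob
detection (σ = expected radius/√2) with non-maximum suppression at the
blob scale, keeping the stronger response on ties; the threshold is
`median + 10·MAD` of the response image, which returns zero detections
on structure-free frames. Flux objects are segmented against the
baseline: per-pixel mean and SD over the six pre-stimulation frames,
foreground where intensity exceeds `mean + k·SD` (k = 3) in at least 3
post-stimulus frames. Two robustness choices matter here and are the
package's own: per-pixel SDs estimated from six frames are floored at
the field-median SD, and the ≥3-frame requirement suppresses the
speckle a literal any-frame 3σ rule would produce over ~126 post-
stimulus frames (about 15 % of background pixels would fire at least
once, enough for spurious speckle to percolate past the size filter).
Components with equivalent diameter < 5 µm are removed (the customary
5-micron minimal size filter is read as an equivalent-diameter
criterion; an area reading would be far more permissive), and
border-touching components are dropped when edge exclusion is on. The
detection window deliberately includes the ionomycin frames so that
every viable cell — including calcium nonresponders — yields a trace
for classification and viability QC.

Traces apply `CTCF = IntDen − area_px × mean field background` exactly,
with the field background defined as the per-frame mean over pixels
outside the union of all object masks (configurable to a fixed ROI).
F0 is the mean CTCF over the six baseline frames; traces with F0 ≤ 0 or
any saturated mask pixel are flagged invalid and excluded with a
reason rather than divided through. Both CTCF-based and uncorrected
mean intensities are recoverable from the trace object, since reported
mean-fluorescence-intensity figures can be computed either way.

## Classification

The maximal-responder definition is operational: fold over F0 reaches
the threshold (default 4) within 60 s of the stimulus, and the
subsequent plateau deviates from its median by at most 10 %
(`max |x − median| / median`; a CV mode is provided). Two details are
the package's own resolution of under-specification:

* the plateau window opens 15 s (`settleS`) after the threshold
  crossing and closes one frame before ionomycin. Starting the window
  at the crossing itself would score the rising edge against the
  plateau and reject genuinely sustained responders whose rise spans
  more than one frame — under the piecewise kinetics above, a maximal
  cell crosses 4× at ~4.6 s post-onset while still ~23 % below its
  plateau;
* the fold threshold defaults to 4 (reported conventions for this assay
  vary between 3× and >4×; the parameter is exposed).

Transient means the threshold was reached in the window but the signal
later fell below half its peak; gradual means it was reached only after
the window; nonresponder otherwise. The non-maximal taxonomy is
nomenclature of convenience — only the maximal class feeds the
dose-response statistic. Cells whose ionomycin-window peak fold is
below 2, or that are viability-stain positive, are reclassified
nonviable and leave every denominator.

## The setpoint fit

Each dose contributes an exact integer ratio
(n_maximal / n_total viable). The 4PL is parameterized on log10 dose
with a Hill slope, bounds 0 ≤ bottom ≤ top ≤ 1 and hill > 0, and fitted
by bounded Levenberg–Marquardt least squares with six deterministic
starts (bottom/top from the data range, log EC50 from the half-range
dose, Hill ∈ {0.5, 1, 2, 4, 8}); binomial (n-weighted) weighting is the
default since per-dose cell counts differ. Reported fits of this curve
typically name neither software, weighting nor constraints; these
choices are the package's. Degenerate tables (fewer than 3 distinct doses, flat
proportions) return an explicit non-identifiable fit instead of an
error or a fabricated EC50; with 3 points the bottom is constrained to
0 and the result flagged non-identifiable. The bootstrap interval
resamples each dose binomially and refits; it is seeded and reported as
a percentile interval.

## Registration and colocalization

Live/fixed alignment uses the nuclear channels: Hann-windowed phase
correlation gives the translation with parabolic sub-pixel refinement;
rotation is found by a coarse 0.5° grid over ±5° on the correlation
peak height followed by golden-section refinement. On synthetic pairs
the recovery error is well under 0.5 px and 0.5°.

Colocalization reports Pearson's R with Costes automatic thresholds:
the candidate threshold walks down the orthogonal (total least squares)
regression line of channel B on A in 1-intensity-level steps until the
correlation of sub-threshold pixels reaches ≤ 0. When the channels are
not positively correlated, or the criterion fires immediately and
leaves no meaningful colocalized set (< 0.1 % of pixels), the
thresholds are flagged undefined. Significance uses 10 block-scramble
randomizations of channel A (block size defaulting to the 12-µm mean
cell diameter, blocks permuted without rotation) and
`p = (1 + #{R_rand ≥ R_obs}) / (1 + n)`, so perfect colocalization
yields p = 1/11. The "flux-positive" image for this comparison is the
single frame 2 min post-stimulation minus the per-pixel baseline mean,
clipped at zero. Where multiple optical depths are available, per-depth
R values and their mean are reported rather than guessing how they
should be combined.

## PTH suppression and decay

Fixed-field PTH is quantified two ways, matching the two customary
metrics: Hoechst-normalized mean fluorescence intensity (the default
for fold suppression, `reference/challenged` so that values > 1 mean
suppression) and field-median per-object integrated density, both after
subtracting an isotype-control background threshold with negative
pixels clipped to zero for that step only. Circulating PTH decay is
fitted as `P(t) = plateau + (p0 − plateau)·e^(−kt)` by bounded
least squares with multi-start on k (plateau free with lower bound 0 by
default; a plateau-fixed-at-0 mode exists); half-life = ln 2/k.
Constant or rising series return converged = FALSE with a diagnostic.
`percentDecrement` offers both a *drop* (100·(1 − P(t)/P(0))) and a
*residual* (100·P(t)/P(0)) reading with linear interpolation, because
reported decrement figures are not always reconcilable with a single
formula/time reading and the package makes no equivalence claim.

## Numerical and scale choices

* Coordinates are 0-based µm with a pixel-centre convention; the pixel
  side is derived as field size / image size (606.1/512 ≈ 1.18 µm; a
  quoted per-pixel area of 1.19 µm² for this configuration is
  internally inconsistent with that and the derived value is used).
* Movie arrays are stored as integers within the declared bit depth;
  TIFF round trips are lossless, and the JSON sidecar
  (`calsens-movie/1`) carries metadata plus optional ground truth.
* Tests and the acceptance script run the full-length 132-frame
  acquisition at a 256-pixel grid for the heavy end-to-end studies
  (8 doses × 600 cells, 20 replicates) and the native 512-pixel grid
  for spot checks; detection and classification results agree across
  the two grids because all filters are stated in physical units.
* Known limitations: no overlapping-cell segmentation (watershed is off
  by default because generated scenes are separable); no bleaching or
  ratiometric correction; registration assumes rigid motion; the
  Costes search assumes 8-bit-like discrete intensity steps.
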