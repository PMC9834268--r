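---
title: "dropscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dropscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package models

`dropscreen` analyses anchored-droplet microfluidic tumoroid screens. A chip
holds a hexagonal array of trapping anchors (154 by default) in a 2 cm^2
chamber; each anchor immobilises a ~50 nL droplet seeded with ~50 tumour
cells that aggregate into one spheroid. A secondary ~14 nL droplet carrying a
drug plus a combinatorial fluorescent barcode is merged into each primary
droplet, diluting library contents by (v1+v2)/v2 = 64/14 ~ 4.57 (the commonly
quoted v1/v2 approximation, 50/14 ~ 3.5, is reported alongside). Multichannel
microscopy (brightfield; CF350/"blue", CF488A/"green", CF647/"red" barcode
dyes; propidium iodide at 555 nm) is the only readout: the pipeline detects
anchors, decodes each droplet's treatment, segments the spheroid, scores
pixel-level death, and aggregates growth, dose-response and
immune-cytotoxicity statistics.

Because no public image data accompany this assay, the package ships a
ground-truthed synthetic renderer. Every stage is validated against that
renderer; what a green test establishes is internal consistency of the whole
chain (simulate -> detect -> decode -> segment -> score -> aggregate), not
performance on any particular microscope.

## Chip geometry

`build_hexagonal_layout()` fills a rectangle of the stated chamber area
(aspect 2:1 by default; the chamber shape is not published, and any convex
shape would do — a rectangle makes the row-major lattice fill trivial) with a
triangular lattice, truncated row-major to the requested anchor count. The
published numbers are the anchor count (154; the abstract's round "150" is
accepted via configuration), the chamber area and an anchor height whose
printed unit ("165 mm") is dimensionally implausible; we carry it as 165 um
of metadata that the 2-D pipeline never uses. Pitch (1,000 um) and anchor
radius (250 um) are unpublished and chosen so 154 anchors tile 2 cm^2 with
~10% margin and each anchor holds one ~460 um (50 nL) droplet. The dual-zone
anchor (circular strong trap + triangular weak trap) is carried as a metadata
flag only; trapping physics is out of scope.

Loading arithmetic is exact and exposed: 1e6 cells/mL x 50 nL = 50
cells/droplet, x 154 anchors = 7,700 cells/chip.

## Barcodes and decoding

The default codebook mirrors the published design: 10 conditions from three
dyes, CF647 and CF488A at 20.0/2.5/0.32/0.04 umol/L and CF350 at 300/50
umol/L. The published text does not enumerate the 10 level-combinations; we
use 4 red-only + 4 green-only + 2 blue-only codes because it matches both the
count and the one-colour-per-drug figure display (red = tamoxifen ladder,
green = alpelisib ladder, blue = DMSO vehicle). Any codebook can be loaded
from CSV.

Decoding reads the per-channel median in a fixed window at the droplet
centre, subtracts the calibration background, divides by the gain, multiplies
by the merge dilution factor (the exact (v1+v2)/v2 convention), and
classifies each dye independently to the nearest ladder level in
log-concentration. The ladders are ~8-fold, so log-space bands are
equispaced; the "absent" class sits one mean ladder spacing below the lowest
level, making its decision boundary the geometric midpoint below that level.
The level vector must match a code exactly; otherwise, or when the log-space
margin between the best and second-best codes falls below 10% of the ladder
spacing, the droplet is UNASSIGNED rather than guessed. Whether the original
analysis decoded pre- or post-merge is not stated; we decode post-merge with
the dilution applied, and the choice is immaterial when render and decode use
the same factor (a tested invariant).

Calibration (gain, background per channel) comes from configuration; with
synthetic data it is the renderer's own optics model. No spectral unmixing is
attempted — the assay was reported free of crosstalk, so crosstalk exists
only as an optional simulator term.

## Segmentation and viability scoring

Anchors are found by correlating the brightfield plane with a zero-mean ring
kernel (FFT-based, replicate-padded), keeping peaks more than 8 robust sigmas
above the correlation background with non-maximum suppression, refining to
sub-pixel by quadratic interpolation, and — when a layout prior is given —
fitting a rigid similarity transform (iterated closest point + Procrustes)
and snapping the lattice through it. A blank image has no 8-sigma peaks and
raises a detection-failure error, as does recovering fewer than half the
expected anchors.

Spheroids are segmented per anchor inside the inscribed disc of the anchor
interior (the ROI keeps the bright anchor ring in the crop corners from
capturing the threshold): Otsu two-class threshold, hole filling, largest
connected component, then morphological selection on area and circularity.
Because Otsu splits even pure noise, a split is only accepted when the
between-class separation exceeds 8 pooled within-class standard deviations
(thresholding Gaussian noise separates classes by only ~2.7), which makes
"empty droplet -> no spheroid" a first-class result rather than an error.
Circularity uses 4*pi*A/P^2 with the taxicab boundary length corrected by
pi/4 (Cauchy's projection formula; exact for discs on average), clipped to 1.
The selection bounds (area 1,000-200,000 um^2, circularity >= 0.6) are
unpublished in the original protocol; ours derive from the synthetic spheroid
size range and are configuration-exposed. Diameter is the equivalent-circle
diameter `2*sqrt(A/pi)`; whether the original figures used equivalent-circle
or Feret diameter is not stated.

Death is scored against a local background: `median + k*MAD` (consistency
constant 1.4826, k = 3 — the standard robust outlier cut; no published value
exists) over crop pixels outside the mask dilated by a 5 px guard band.
`dead_fraction = dead_pixels / area`; `viability = 1 - dead_fraction`. The
published definition sentence is garbled ("respectively the number of dead
pixels and the area of the spheroid"); this ratio is the only reading
consistent with the viability panels. `mean_dead_intensity` (mean PI over the
mask) is carried separately because the dose-response figure reports that
statistic. On immune arms, CFSE-positive pixels (above their own local
background threshold) are excluded from the dead count so labelled
lymphocytes are not scored as dead tumour cells — the original verification
of this was visual only.

## The synthetic world

The generator's defaults are the published conditions wherever one exists
(anchor count, chamber area, droplet volumes, dye ladders, cell loading, PI
at 0.3 umol/L, 10:1 CD8+:tumour ratio, 1/24/48 h co-culture schedule).
Everything else is a documented choice:

* **Growth** is logistic (the simplest saturating model with two
  interpretable parameters): 80 um at seeding, plateau 250 um, rate 0.05/h,
  lognormal anchor-level size noise (sdlog 0.08). The published figures show
  diameter trajectories without numeric axes in the text, so these magnitudes
  are plausible rather than calibrated. Diameters are capped at 90% of the
  droplet diameter — a spheroid cannot outgrow its droplet.
* **Dose-death** is a Hill curve on the delivered (post-merge) dose with
  first-order onset (tau = 24 h) and Beta-distributed anchor noise
  (concentration 80). Default parameters reproduce the reported phenotype:
  tamoxifen kills only at the top of its ladder (post-merge EC50 25 umol/L,
  slope 4), alpelisib — a growth inhibitor — induces no death.
* **Co-culture killing** is saturating first-order,
  `d(t) = baseline + (max-baseline)(1-exp(-k_eff t))` with `k_eff`
  proportional to the effector ratio (normalised to 10:1), so killing is
  always front-loaded: the 0-24 h increment exceeds the 24-48 h increment for
  every k > 0, matching the reported kinetics qualitatively.
* **Optics** are linear: `counts = gain x concentration + background +
  N(0, sd)`, 16-bit quantisation. Gains put the top post-merge dye levels
  near 60,000 counts and give signal-to-noise ~20 at the weakest red/green
  level — separability, not microscope realism, is the goal, and no
  gain/noise figures are published. The PSF sigma defaults to **zero**: the
  spec-fixed scoring rule (median + 3 MAD) sits only ~2 robust sigmas above
  background, so any blur bleeding from randomly scattered single-pixel PI
  signal crosses it and biases dead fractions upward. Blur is supported
  (`psf_sigma > 0`) for studying detection robustness; ring and disc
  detection tolerate it, pixel-level death scoring by a hard local threshold
  does not, and that trade-off is inherent to the scoring rule, not to the
  implementation.
* **Dead pixels** are a seeded random subset of spheroid pixels of size
  `round(f x area)`, matching the pixel-count readout; no per-cell model.
* **Empty anchors** occur with configurable probability (default 0).

What the generator does **not** emulate: uneven illumination, focus drift,
spectral crosstalk, debris, droplet merging failures, spheroid eccentricity,
necrotic-core intensity gradients. A green end-to-end test therefore
establishes algorithmic correctness under the stated statistical structure,
not robustness to those artefacts.

## Statistics

`two_way_anova()` is implemented from sums of squares, not delegated:
residual sums of squares of nested dummy-coded least-squares fits give Type
II sums `SS(A|B)`, `SS(B|A)`, `SS(AB|A,B)`, identical to the textbook
decomposition on balanced designs (the tests verify equality with an
explicit 2x2 hand computation to 1e-10 and with the linear-model oracle on
random balanced designs). Cells must be non-empty (the error names the
offending cell) with >= 2 replicates; zero residual variance is an explicit
degenerate-input error. Its type-I error over 1,000 null simulations is
checked to lie in [0.03, 0.07]. No multiple-testing correction is applied on
the main path, mirroring the original analysis; `pairwise_vs_control()`
offers opt-in Holm-adjusted annotations.

Aggregations: `dose_response_summary()` (mean +- sd of mean dead intensity
and viability per dose), `growth_curves()` (median/IQR per condition and
timepoint), both excluding QC-flagged rows. UNASSIGNED anchors stay in the
screen table but never enter condition-level statistics; excluding an anchor
provably leaves every other anchor's statistics untouched (tested). Growth
time-course viability is reported unnormalised (whether the original
normalised to t0 is unstated); normalise downstream if desired.

## Numerical and I/O choices

* Images are numeric matrices (rows = y); pixel coordinates are 0-based with
  `px = um/pixel_size - 0.5` at pixel centres. Default calibration 10 um/px.
* On-disk stacks are 16-bit binary PGM planes plus a YAML sidecar: the
  environment provides no TIFF writer for R, and 8-bit PNG would destroy the
  512-fold barcode dynamic range. PGM is plain, standard and lossless here
  (verified by a round-trip test).
* Otsu's threshold returns the upper edge of the argmax histogram bin so a
  narrow intensity mode is never split through its middle.
* The hexagonal lattice check uses a 1e-6 relative tolerance on
  nearest-neighbour distances; merge-dilution mass balance is exact to 1e-12
  relative.
* Seeds are mandatory for every stochastic operation; identical seeds give
  bit-identical truth tables and rendered images.

## Known limitations

Single 2-D plane per channel (no z-stacks); no single-cell resolution inside
spheroids; no drug effect on growth rate (only on death) in the simulator;
detection assumes a rigid (similarity) deformation of the lattice; the
morphology bounds and optics defaults are synthetic-world choices that a real
deployment must recalibrate from control wells.
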