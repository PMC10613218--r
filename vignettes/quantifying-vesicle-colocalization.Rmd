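---
title: "Methods: vesicle detection, line-profile colocalization and contact-site quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vesicle detection, line-profile colocalization and contact-site quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesicoloc)
```

This vignette is the package's account of its methods: the models and
rules it implements, the parameters that matter, the decisions taken
where the procedure admits more than one reasonable reading, and what
the synthetic-data tests do and do not establish about real microscopy
data.

## The measurement problem

Multivesicular endosomes (MVEs) appear in confocal fluorescence images
as bright, roughly 1 µm puncta in a vesicle channel (CD63). The
questions the pipeline answers are per-cell and per-vesicle: how many
MVEs are there; what fraction carries a second marker (an exocyst
subunit such as Exo84, or a phosphoinositide reporter such as GFP-P4C
for PI(4)P or GFP-FYVE for PI(3)P); which vesicles sit at
mitochondrion–MVE contact sites (MMCS), and how are those contacts
distributed between the perinuclear and peripheral cell regions. A
companion module post-processes 3D single-molecule localization data of
the same structures into density renderings.

## Intensity normalization

All profile scoring operates on 8-bit images, because the signal cutoff
(100) is defined on that scale. `to_8bit()` applies a fixed linear
display window per channel: values at or below `low` map to 0, at or
above `high` to 255, with round-half-up in between. The window is an
explicit, logged configuration value; `auto_display_range()` computes it
from the first image of a batch and the pipeline then freezes it for the
whole batch, so that all conditions are converted with the same
settings. The mapping is assumed linear. Rounding is round-half-up and
is tested, because downstream peak areas are sums of 8-bit values and
would silently change under a different rounding rule.

Pixel coordinates are 0-based throughout and refer to pixel centers.

## Spot detection

The detector is a scale-tuned Laplacian of Gaussian. For an estimated
object diameter $d$ the filter scale is $\sigma = d / (2\sqrt{2})$ — the
standard radius-to-scale convention under which a Gaussian blob of sd
$\sigma_b$ maximizes the scale-normalized response
$-\sigma^2 \nabla^2 (G_\sigma * I)$ exactly when $d = 2\sqrt{2}\,
\sigma_b$. This law is enforced by a sweep test. The discrete kernel has
its mean subtracted so constant images give exactly zero response;
borders are handled by reflection. Defaults are $d = 10$ px with quality
threshold 4 for CD63-like vesicles and $d = 6$ px with threshold 12 for
EEA1-like structures.

Two caveats are deliberate:

* The numeric thresholds 4 and 12 live on the intensity scale of the
  original acquisition software; the package's quality (the
  scale-normalized response at the maximum) is not comparable in
  absolute terms. For any new data — including the synthetic scenes —
  `calibrate_quality_threshold()` derives a threshold from the noise
  floor: the 99.9th percentile of the blank-image response *local
  maxima* (maxima, not pixels, because detections are maxima and the
  null distribution of maxima is the relevant one), times a safety
  margin of 2. Genuine diffraction-limited spots respond a factor of
  ~50 above this floor, so the margin costs no sensitivity.
* Touching vesicles that the detector fails to separate are flagged
  (`merged_flag`: the connected supra-half-maximum response support
  exceeds 1.5× that of a single matched spot) but never split
  automatically — the original procedure resolved these by eye, and
  replicating that judgment would be guesswork. Both flagged and
  unflagged counts are available.

For z-stacks, detection runs per plane and `count_vesicles()` merges
coincident detections across planes before counting inside the cell
mask, matching a workflow that acquires confocal z-stacks but
quantifies in 2D.

## Line-profile colocalization

For each vesicle a straight line of 40 samples at 1-px spacing is
centered on the detection; intensities are sampled by bilinear
interpolation, and samples falling outside the image are marked missing
and excluded. A *signal peak* is a maximal run of samples strictly above
the cutoff (100); a run touching exactly 100 is not a signal. Peak
*area* is the raw intensity sum over the run (an `area_mode` flag
switches to the cutoff-subtracted sum). The vesicle peak is the run
containing the profile midpoint, or failing that the nearest run; the
marker peak is the marker-channel run with maximal support overlap with
the vesicle peak (ties to the larger area, then leftmost). The overlap
area is $\sum \min(v_k, m_k)$ over the support intersection — the
natural area of overlap of two curves; a `support-length` mode is
available. The call is positive iff the overlap area strictly exceeds
half of the marker peak area; a share of exactly 0.5 is negative. An
exhaustive small-instance test (all three-level length-10 marker
profiles) and 10^4 random length-40 profiles pin the implementation to a
brute-force oracle, including the flip at exactly one half.

**Line direction.** "A line drawn across each vesicle" does not fix an
orientation. The package offers four modes: the local intensity
principal axis of the vesicle channel (`principal-axis`, the default of
`profile_config()`), a marker-seeking mode (`toward-marker`: from the
vesicle center through the brightest marker pixel within 4 px), a
`toward-reference` mode (used for contact profiles, where the target is
the nearest mitochondrion), and `fixed-angle`. The pipeline scores
markers with `toward-marker`: marker puncta occupy discrete spots on the
MVE surface, offset from the vesicle center, and an operator drawing a
line across a vesicle to assess marker positivity naturally orients it
through the visible marker signal. A vesicle-channel principal axis is
blind to that offset and misses puncta lying perpendicular to it, which
systematically depresses the estimated positive fraction; the
marker-seeking direction removes that bias while leaving negative
vesicles untouched (aiming at a noise maximum far below the cutoff
cannot create a positive call).

`quantify_profile_intensity()` reuses the same rule to report the
reporter-channel peak area overlapping the vesicle peak, the per-MVE
phosphoinositide signal used for PI(3)P/PI(4)P comparisons.

## Contact sites and regions

For MMCS scoring each vesicle gets a 50-px profile toward the nearest
mitochondrion-mask pixel (Euclidean; ties broken lexicographically by
(y, x); a vesicle already inside the mask points along the outward
boundary normal). A contact is called when the vesicle-channel and
mitochondria-channel signal runs overlap on the line. The background
level that defines a "signal" is not a universal constant; by default
each channel's threshold is mean + 2 sd of the pixels outside all
detected objects, with a fixed numeric threshold (e.g. the profile
cutoff 100) available via `background=`. A stricter mode additionally
requires both channels above threshold at a common sample; the default
is the literal overlapping-runs reading.

The perinuclear region is the disk of **twice the nuclear diameter**
(i.e. radius = one nuclear diameter) centered on the nucleus centroid,
intersected with the cell mask; the rest of the cell is peripheral. For
non-circular nuclei the diameter is the equivalent-area circle diameter
$2\sqrt{A/\pi}$, which is the only reading that is well defined for an
ellipse. Contacts are localized at the vesicle anchor — the vesicle is
the counted object.

The EM rule takes annotation tables (object class, center, radius, ILV
count) and calls a direct contact when the **boundary-to-boundary** gap
(center distance minus both radii, for circular annotations) is smaller
than the mean MVE radius of the image. Boundary gap, not center
distance, is used because the rule compares a distance against a radius;
overlapping boundaries (negative gap) are always contacts, and the rule
is monotone in the mean radius.

## Localization rendering

Localization tables in nm are divided by a configurable `scale_factor`
on XYZ export (legacy integer preset 15) and written as uranium
pseudo-atoms with 3-decimal coordinates; the comment line records the
scale and the nm-per-unit interpretation (13.46 nm preset), because the
two conventions are not mutually consistent for every source unit and
provenance must travel with the file. Density volumes are sums of
isotropic 3D Gaussians of sd `sigma_factor × resolution` (defaults
1.5 × 1.4 output units), each normalized to unit integral —
mass-weighting, which an atomic-density renderer would apply, is
deliberately off so the grid integral equals the localization count
(conservation is tested to 1%, and voxel values against the closed-form
Gaussian sum to 1e-6 relative). The grid covers the bounding box plus a
4σ margin; grids coarser than σ are refused rather than silently
aliased. Dust filtering is point-based: a localization survives iff
another localization lies within the dust radius (60 nm default, the
~1.5-voxel criterion of volume renderers). Removal only ever affects
points that are nobody's neighbour, so the one-pass filter is idempotent
by construction; an iterative mode re-evaluates to a fixpoint and a
voxel-component variant is left to future work.

## Statistics

Group comparisons use the classic pooled-variance two-sided unpaired
Student's t-test (df = $n_a + n_b - 2$); Welch's correction is available
by flag but is not the default, matching the stated test. Degenerate
inputs resolve explicitly: zero pooled variance with equal means gives
t = 0, p = 1; with unequal means an infinite statistic flagged
`degenerate`. Whole-image colocalization uses the sample Pearson
correlation over raw (pre-8-bit) intensities; constant channels yield a
missing value, not zero. Z-stacks are reduced by maximum-intensity
projection by default (a single-plane option exists) — the choice
matters little for flat cells and is recorded in the function signature
rather than hidden. Summaries are reported as mean ± s.d. across cells.

## The synthetic-scene generator

`generate_scene()` renders what the quantification needs to be tested
against: vesicles as isotropic Gaussian spots of sd
$d/(2\sqrt{2})$ (matching the detector's diameter convention; a ring
mode exists for larger endosomes), a marker channel with puncta only on
the true-positive vesicles, offset 2 px from the vesicle center with sd
1.5 px (modeling marker domains on the MVE surface — this specifically
stresses the 50% overlap rule), mitochondria as jittered random-walk
polylines steered to stay inside the cell, an elliptical nucleus, global
Gaussian PSF blur (σ = 1 px), and Poisson shot noise plus Gaussian read
noise on a 16-bit scale. Key defaults encode the emulated study
conditions: 0.1 µm pixels, 1.0 ± 0.1 µm vesicle diameters, a 45%
marker-positive fraction, 20-cell batches of 50 vesicles. The default
canvas is 384 px with six mitochondrial filaments and a 25 px clearance
ring around non-contacting vesicles: large enough that 50 vesicles at
the 2-diameter minimum spacing, the contact quota on the skeleton, and
the clearance constraint can all be satisfied simultaneously, with the
filament count topped up automatically when a seed draws many contacting
vesicles. Amplitude ranges (2500–4500 counts over a 200-count
background) are chosen so that after PSF attenuation and the frozen
8-bit conversion, true puncta land comfortably above the 100 cutoff
while the noise floor stays far below it — intensity distributions are
not reported quantities anywhere, so these are documented assumptions,
configurable per scene.

One stated property of the generator was adjusted for internal
consistency: with spot sd fixed at $d/(2\sqrt{2})$, the rendered FWHM is
$2.355\,\sigma \approx 0.83\,d$, so a FWHM-equals-diameter check cannot
hold to 10%. The test suite instead verifies by moment fitting that the
rendered spot sd matches $\sqrt{(d/(2\sqrt{2}))^2 + \sigma_{PSF}^2}$
within 10%, which validates the same PSF model without asserting an
inconsistent identity.

**What passing tests show — and what they do not.** The synthetic scenes
have homogeneous backgrounds, isotropic Gaussian PSFs, well-separated
vesicles (except in the deliberate crowded preset), stationary noise and
perfectly known truth. Success on them demonstrates that the
implementation applies the stated rules exactly, that the estimator of
the marker-positive fraction is unbiased and consistent under those
conditions, and that contact calls track planted geometry. It does not
demonstrate robustness to uneven illumination, autofluorescent clutter,
chromatic offsets between channels, out-of-focus haze, or densely packed
endosomal fields — on real data those remain the responsibility of
acquisition quality and the operator's display-range and threshold
choices, which the package requires to be explicit and logs with every
run.

## Numerical choices and problem sizes

Round-half-up for 8-bit conversion; bilinear interpolation for oblique
profiles with edge-clipped samples treated as missing; reflective
padding for all convolutions; strict inequality at the cutoff and at the
50% overlap share; lexicographic (y, x) tie-breaks for nearest-pixel
searches; leftmost-peak tie-breaks in profile scoring; one seeded RNG
per scene with per-cell seeds derived from the run seed. The shipped
tests use 128–384 px scenes, batches of 20 cells × 50 vesicles for
fraction recovery, 3^10 exhaustive plus 10^4 random profiles for the
overlap oracle, and 200-seed replicates for the binomial check — sizes
chosen so the full suite exercises every rule at scales where exhaustive
oracles are still feasible.

## Known limitations

Detection is 2D-per-plane with z-merging, not a true 3D blob search.
Quality values are not comparable across instruments without
calibration. The merged-vesicle flag marks but does not resolve
doublets. The density renderer omits atomic-mass weighting and the
voxel-connectivity dust variant. The EM contact rule assumes circular
annotations when only radii are given. None of these affect the rule
definitions themselves, which are isolated in small, individually tested
functions.
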