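---
title: "Quantifying silver-stained nucleolar organizer regions: morphometry, fractal dimension, and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying silver-stained nucleolar organizer regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agnorfd)
```

## The measurement problem

Argyrophilic nucleolar organizer regions (AgNORs) are silver-stained
aggregates of nucleolar proteins that appear as small, near-black dots
inside cell nuclei on brightfield histology. Their number, size and shape
track ribosomal transcription and hence proliferative activity, which makes
them attractive quantitative markers in prostate pathology, where the
diagnostic groups of interest range from benign nodular hyperplasia (BNH)
and atypical adenomatous hyperplasia (AAH) to acinar adenocarcinoma of
Gleason patterns 2 through 5.

Classical Euclidean descriptors (areas, diameters) flatten much of the
morphological signal. This package complements them with scale-invariant
descriptors: the box-counting fractal dimension (FD) of each dot's
silhouette, which measures boundary complexity, and the FD of the
skeleton-filtered whole-image dot map, which measures how dots repartition
across the glandular architecture. A planar set has FD between 0 and 2; a
smooth outline sits near 1, and increasingly rugged outlines drift upward.

The pipeline is: segment dots from RGB images by explicit colour and
intensity rules; measure each object (area, roundness, silhouette FD);
reduce the whole-image dot mask to a pruned skeleton and measure its FD;
filter degenerate values; then compare groups through hierarchical
averaging, one-way ANOVA with Tukey HSD post hoc tests, Pearson
correlations between tissue compartments, and a narrowed-interval FD
frequency analysis.

## Segmentation model

The silver reaction product is darker than every other chromogen in the
staining design (a red nuclear counterstain, a green basal-cell chromogen
in benign glands, pale stroma). The default rule marks a pixel as AgNOR
when its mean RGB intensity falls below `darkness_threshold` (default 90
of 255) *and* it is not dominated by the green chromogen (green exceeding
both red and blue by more than `green_margin = 25`). The mask is cleaned
by an optional morphological opening (off by default: a radius-1 opening
distorts the one- and two-pixel boundary features that the silhouette FD
measures) and by removing components smaller than `min_object_px = 4`.

Two conventions are fixed package-wide and stated here because results
depend on them: foreground components are 8-connected (background
4-connected), and coordinates are 0-based row/column with pixel centers on
integer positions. Labels are assigned in raster order, so output tables
are stable across runs.

No texture features enter the default rule. Texture is listed as an
extension point rather than implemented, because any concrete texture
operator would be an invention the rest of the pipeline does not need:
on both synthetic material and well-stained sections, darkness plus
chromogen exclusion is sufficient (object-level precision and recall are
above 0.95 on noise-free synthetic frames, and exact on the shipped
30-dot fixture).

## Morphometry

**Roundness** is the diameters ratio: the ratio of major to minor axis of
the second-moment-equivalent ellipse, computed from the eigenvalues of the
pixel covariance matrix with a 1/12 per-axis variance correction for the
unit pixel. A circle scores 1.00 (±0.02 in calibration), a 2:1 ellipse
2.00 (±0.05), and the measure is rotation- and scale-invariant within
raster tolerance. Objects under 5 pixels do not define the fit and are
flagged degenerate. An isoperimetric alternative
(perimeter² / 4π·area) is available behind `method = "circularity"` for
comparison with software that reports that convention; all package
results use the diameters ratio.

**Areas** are reported both in pixels and in µm² (pixel area ×
pixel_size²; the default calibration is 0.17 µm/px, typical of a 40×
objective on this camera class, and is configurable everywhere).
The **total normalized area** of an image is AgNOR-positive pixels over
total pixels, scaled by 10⁶; it is dimensionless and independent of the
calibration. **Density** is dots per mm².

## Fractal estimation

`box_count_fd()` bins foreground pixels into grids of box sizes 2, 4, …,
up to a quarter of the short mask side (at least three sizes are
required), and fits log N(s) against log (1/s) by least squares; the slope
is the dimension estimate and R² is reported as fit quality. Two numerical
choices matter:

* The grid is anchored at the content's bounding box, which makes counts
  — and therefore the estimate — exactly invariant under translation of
  the mask. Offset minimization alone (the common alternative) leaves a
  residual dependence on where a dyadically self-similar set happens to
  sit relative to the grid that can move the estimate by more than 0.1.
* At each size the count is the minimum over a 4×4 grid of fractional
  offsets, which removes most of the remaining placement bias.

Calibration: a 512-px line estimates 1.00, a filled 512×512 square 2.00,
and an order-7 Sierpiński triangle rasterized at 512 px estimates 1.63
against the closed form log 3 / log 2 ≈ 1.585. The small positive bias is
a property of the fixture, not the estimator: at 512 px each of the 3⁷
cells spans 4 px, and below that cell size the set is locally
plane-filling, which steepens the first octave of the fit. Counts at every
size agree exactly with an exhaustive grid-overlay recount.

**Silhouette FD.** Per object, the boundary (the object minus its one-pixel
8-connected erosion) is box-counted on the padded bounding box with sizes
1, 2, 4, … Objects whose boundary has fewer than 8 pixels or that support
fewer than three sizes are flagged with the sentinel FD = 1, which the
value filter later removes — this makes the exclusion of sub-resolution
particles explicit rather than silent. Smooth disks estimate ≈ 1.0; the
estimate rises monotonically with the boundary perturbation amplitude of
the synthetic dots, which is the property the group comparisons rely on.

**Skeletonization.** Whole-image dot masks are thinned with the Zhang–Suen
algorithm and spur branches are pruned by iterative endpoint removal
(default `prune_length_px = 5`; the value is a free parameter of the
method and 5 px removes raster-artifact spurs without consuming genuine
branches at the default dot scale). Zhang–Suen erases small compact blobs
entirely — its well-known 2×2 artifact — so any source component that
vanishes is restored as a single pixel at its medial residue (the
foreground pixel nearest the component centroid). The skeleton therefore
always has exactly one component per source component, which is asserted
in the tests: a filled disk reduces to its center, an annulus to a closed
one-pixel loop that preserves the hole.

**Skeleton FD** is the box-counting dimension of that skeleton map,
measured on a coarse ladder (boxes from 8 px up): fine boxes would measure
fragment shape, while the quantity of interest is how dots repartition
across the field. Dots packed along a line estimate near 1; dense
scattered dots estimate well above that. A map whose skeleton has fewer
than 8 pixels is flagged degenerate.

## The value filter

Before any statistics, objects with zero area, undefined or zero
roundness, or FD equal to 1 (within 10⁻⁶) are removed. This is the
explicit exclusion rule for the smallest, unequivocally stained particles;
it is idempotent and order-preserving, and both the object tables before
and after filtering are reported in the run summary.

## Statistics layer

Measured values are averaged strictly hierarchically — images within
patient, patients within group — never by pooling pixels or objects across
levels. The ANOVA unit defaults to the image (with a patient-level option)
because per-image collages are the natural replicate for this design;
six-group ANOVAs are always accompanied by the pooled three-level
comparison (BNH, AAH, carcinoma = G2–G5). Unbalanced designs use the
Tukey–Kramer form of the HSD automatically. The test suite checks the
ANOVA and Tukey implementations against an independent sums-of-squares /
studentized-range computation to 10⁻⁸ on random fixtures, and verifies
that the pipeline's type-I error on null cohorts (all six groups generated
from an identical specification) stays within [0.03, 0.07] at α = 0.05
over 1000 simulated cohorts.

The FD frequency analysis histograms per-object silhouette FDs by group
and runs the ANOVA twice: on all values and on the values inside the
narrow interval [1.05, 1.09] where the frequency distributions
concentrate. Both endpoints are inclusive; narrowing is a pure subset
filter. Discarding the heavy, group-unspecific tails in this way can
recover group structure that the full-range test dilutes, and the
acceptance suite demonstrates exactly that construction: adjacent group
means two pooled standard deviations apart inside the interval are
detected at p < 0.001 while the full-range ANOVA on the same data stays
above 0.05.

Every output artifact (object and image CSVs, the statistics JSON)
embeds the hash of the configuration that produced it, and the statistics
stage can be rerun from the persisted image-level CSV without repeating
segmentation — the tables themselves are the cache, which keeps the
pipeline stateless.

Compartment analyses (epithelium versus complete tissue, via Pearson
product-moment correlation of per-image values) require an explicit
compartment map — the synthetic ground truth or a user annotation. The
package never guesses compartments heuristically.

## The synthetic generator

No imaging study ships its slides here, so validation runs on a seeded
synthetic generator with exact ground truth. It emulates the statistical
structure the method is meant to detect, not microscope physics:

* near-black dots rendered as ellipses with sinusoidal radial boundary
  perturbation r(θ) = R(1 + a·sin(hθ + φ)) — one amplitude parameter `a`
  controls silhouette complexity, one aspect-ratio parameter controls
  roundness;
* red-rendered nuclei, either placed on ring contours around gland lumina
  ("glandular") or uniformly ("disorganized"), with a green basal band
  around benign glands matching the staining design;
* optional stromal dots outside the glands, Poisson dot counts per
  nucleus, Gaussian pixel noise, and composite captures built as 4×6
  grids of tiles.

Dots are placed with a guaranteed two-pixel boundary gap (enforced on the
rendered rasters by a compiled collision kernel), so every ground-truth
object is exactly one 8-connected component of the dot mask — the property
all recovery tests key on. Identical specification and seed give
bit-identical images; cohorts derive per-image seeds deterministically
from one master seed.

The default group conditions encode the qualitative structure reported
for this pathology: carcinoma groups get dots closer to circular (aspect
1.30–1.35 versus 1.55–1.60 benign), smoother boundaries (amplitude
0.12–0.20 versus 0.28–0.30), disorganized architecture for high Gleason
patterns, and mildly rising dot counts with pattern. What the generator
does **not** emulate — stain variability, focus drift, stitching seams,
overlapping nuclei, nucleus segmentation errors — bounds what passing
tests can claim: they validate the measurement and statistics chain, not
robustness to real-slide artefacts.

Where the acquisition geometry is unrecoverable from the study design the
frame size is a free parameter; the default is a 256-px frame with 8
nuclei of radius 20 px at 0.17 µm/px.

## Problem sizes used in the validation studies

The simulation studies in the acceptance suite use reduced frame
geometries, chosen once as the package's own study conditions:

* parameter recovery: 100 cohort replicates of 50 images per group
  (300 images each) at 96-px frames with 3 nuclei per frame and default
  dot morphology; success requires pooled-carcinoma silhouette FD below
  both AAH and BNH at Tukey-adjusted p < 0.01;
* null calibration: 1000 cohorts of 3 images per group at 72-px frames
  with 3 nuclei per frame, ANOVA on per-image dot counts;
* narrowed-interval power: 6 groups × 200 FD values (50 in-interval,
  150 tail values per group).

## Known limitations

* Nucleus masks come from ground truth or user annotation; the package
  does not segment nuclei from real images.
* The box-counting estimate of small objects is coarse (three to four
  scales); it is used comparatively, and absolute per-object FD values
  below ~12 px of boundary should not be over-interpreted.
* The skeleton FD of sparse dot maps reflects scatter density as much as
  architecture; comparisons are only meaningful at matched dot counts.
* Group averages of unbalanced cohorts weight patients equally by design;
  this is a modelling choice, not an estimator of the pooled-image mean.
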