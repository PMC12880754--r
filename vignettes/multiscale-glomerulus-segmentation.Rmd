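---
title: "Multiscale glomerulus segmentation: models, parameters and design choices"
author: "glomscale maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale glomerulus segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hierarchical phase-contrast tomography images an intact human organ at
around 20-25 um/voxel and nested volumes of interest (VOIs) down to a few
um/voxel. Glomeruli — quasi-spherical capillary tufts of roughly 200 um
diameter in the kidney cortex — are unambiguous only at the high
resolutions, yet whole-organ questions (how many glomeruli, how are they
distributed across the cortex, how do their volumes vary by zone) must be
answered on the low-resolution whole-organ scan. `glomscale` implements a
hierarchical answer: train a segmentation model where the structures are
clearly visible, propagate its (cleaned) predictions down the resolution
chain as pseudo-labels via rigid registration, fine-tune at each coarser
level, and run whole-organ morphometry on the final instance map.

Every stage is exercisable without any external data through a synthetic
multiscale kidney phantom with exact ground truth.

## The synthetic phantom

`phantomConfig()` / `generatePhantom()` build an ellipsoidal kidney: a
medulla inside a cortical shell inside a thin capsule/fat rim. Glomeruli
are spheres with lognormal diameter jitter (mean 200 um, sd 15% of the
mean) placed by hard-core rejection sampling — centres uniform over cortex
voxels, a proposal rejected when it would overlap an accepted sphere —
at a target centre density of 9.4 per mm^3 of cortex. The instance count
is the rounded product of density and realised cortex volume, so the
realised density tracks the target up to rounding, and under the default
geometry the mean glomerular label fraction of cortex-centred 128^3
high-resolution crops falls in the few-percent range typical of annotated
training cubes.

Three distractor classes mimic the dominant false-positive sources of
real predictions, each with a deliberately discriminable signature:

* **fat blobs** in the capsule rim: bright but nearly textureless
  (intensity sd 15 on a 16-bit scale), so an intensity-variance lower
  bound removes them;
* **clots** in the medulla: very bright with very high texture variance,
  caught by a variance upper bound or the cortex mask;
* **tubule segments** in the cortex: bright elongated cylinders
  (radius 25-35 um, length 300-500 um) whose sphericity is far below a
  glomerulus's.

The intensity model (class means/sds) is invented: real phase-contrast
reconstruction physics, vascular trees and pathology are out of scope.
The spatial point process is hard-core Poisson; whether real glomeruli
cluster beyond hard-core exclusion is not established here, so passing
phantom tests demonstrates correctness of the machinery, not biological
realism of spatial statistics.

`deriveLowerResolution()` produces the next level of the hierarchy:
Gaussian blur at sigma = 0.5 x factor voxels (standard anti-aliasing),
mapping through a known rigid+scale transform, block-averaging by the
factor; labels and masks are resampled nearest-neighbour and the exact
child-to-parent transform is recorded, giving every downstream stage a
known-truth target.

## Preprocessing

Voxel intensities of phase-contrast volumes are non-quantitative and vary
between samples, so volumes are normalised by slice-wise 2D CLAHE along z
(`applyClahe`, clip limit 0.01 of tile mass, 8x8 tiles, 256 bins — the
common defaults of mainstream implementations) after a linear stretch to
the full bit range, then reduced to 8-bit by linear min-max rescale with
round-half-even (`toUint8`; a constant volume maps to zero). Annotated
cubes are tiled into non-overlapping patches (`extractPatches`); cubes
whose edge is not a multiple of the patch edge are corner-cropped rather
than padded, to avoid fabricating intensities. `splitDataset` draws a 9:1
train/test split per sample with at least one test cube from every
sample; a sample with a single cube is refused rather than silently
emptied of training data.

## Training objective and backbone

The training loss is the ensemble of mean voxel-wise binary cross-entropy
and a weighted soft-Dice term,

$$L = \mathrm{CE}(p, q) + \beta\left(1 -
\frac{2\sum_x p(x)q(x) + \varepsilon_1}
     {\sum_x p(x) + \sum_x q(x) + \varepsilon_2}\right),$$

with beta = 1 and eps1 = eps2 = 1e-5. The printed form of the source
equation writes the Dice numerator as a product of sums and the CE as
"1 - sum p log q"; we read both as typesetting artefacts and implement
standard soft Dice (sum of products) and mean binary cross-entropy —
recorded here rather than silently corrected. Validation Dice is tracked
with an exponential moving average (alpha = 0.9, first epoch equal to the
raw value) and checkpoint selection takes the best-EMA epoch.

The backbone is pluggable behind a two-function contract — fit on
labelled patches, predict per-voxel probabilities on one patch. The
shipped reference backbone is a logistic voxel classifier over fixed
multiscale convolutional features: normalised intensity, Gaussian
smoothings at 20 and 40 um, a difference-of-Gaussians band-pass and a
local standard deviation, trained by momentum gradient descent (momentum
0.9, polynomial learning-rate decay with power 0.9) on the combined loss
with an analytic gradient. Feature scales are fixed in micrometres, not
voxels, so a model warm-started at a coarser level sees the same physical
features its weights encode — this keeps fine-tuning consistent across
the resolution chain and noticeably reduces boundary dilation at the
lowest level. The backbone exists so the full pipeline runs in minutes on
one CPU; it is not a substitute benchmark for large 3D networks, whose
reproduction is explicitly out of scope.

Cross-validation (`runCV`) assigns folds at the level of parent cubes,
never patches, so no validation cube leaks patches into training.
Sliding-window inference (`slidingWindowInfer`) blends overlapping
windows (default 50% overlap) by uniform averaging; blend weights sum to
one everywhere, and sub-window volumes are reflect-padded.

When propagating to coarser levels, pseudo-labelled cube sets are
rebalanced exactly as the source procedure states: at the intermediate
level all non-empty cubes are kept plus a uniform-random 1.05% of the
empty ones; at the lowest level all cubes with label density >= 1% are
kept plus 0.7% of the sparser ones. Counts round half-up (the stated
arithmetic implies 10.5 -> 11) with a minimum of one from a non-empty
pool.

## Instance filtering

Binary predictions become instances by 26-connected components
(`labelInstances`; isotropic grids make the full neighbourhood the
natural choice, and 6-connectivity is available where corner-touching
structures must stay separate). Per instance we compute volume,
equivalent spherical radius, population intensity variance, and roundness
as 3D sphericity $\pi^{1/3}(6V)^{2/3}/A$. The surface area $A$ comes from
a coarea estimator — integrate the gradient magnitude of the smoothed
indicator (sigma 1.5 voxels) — because no marching-cubes surface-area
routine exists in the supporting stack; on digital spheres of radius 10
voxels the estimate is within a few percent, and sphericity is clamped
to (0, 1] with single-voxel instances set to 1 by convention.

Filtering keeps an instance only if all active criteria hold: variance
within bounds, roundness above a floor, equivalent radius at least 62 um
(the minimum credible glomerular radius after ethanol shrinkage,
volume 1e6 um^3, close to the smallest MRI-based measurement of 72 um /
1.6e6 um^3), at least D instance centroids (self included) within an
axis-aligned window of W voxels, and centroid inside the cortex mask.
Filtering is monotone — tightening any threshold never keeps more — and
with no active criteria it is the identity.

Thresholds are chosen by Latin hypercube search (`lhsSearch`): sampling
intervals come from percentiles of the aggregate property distribution
(lower bounds span P1-P30, upper bounds P70-P99), 20 stratified
candidates are drawn, and each candidate is scored by mean Dice over the
evaluation cubes — which may include a glomeruli-free fat cube whose
empty truth scores 1 only when everything in it is removed (hence the
convention Dice(empty, empty) = 1). Within each dimension the lowest
quarter of the unit draw deactivates that criterion; the published
operating points likewise leave different criteria inactive at different
resolutions, and on small evaluation sets an always-active upper bound
would necessarily clip the largest true instance. Ties break to fewer
active criteria, then candidate order. The published real-data operating
points ship as `reference_thresholds.json` for documentation; they are
not targets for the phantom.

Because near-tangent glomeruli coarser than the grid merge into one
component, the pipeline applies `splitTouchingInstances` after
connected components: inside each instance the Euclidean distance
transform to background is computed, cores are components where the
distance reaches 70% of the 62 um radius floor, and multi-core instances
are re-partitioned by descending-distance region growing (marker-based
watershed). Single-core instances pass through untouched, so the step
can only split, never merge. This is the package's own refinement —
standard practice for touching quasi-spherical objects — and it is
exposed as an explicit, separately testable operation.

## Multiscale registration

A higher-resolution moving volume is registered into the
lower-resolution fixed frame by a rigid+isotropic-scale transform about a
pair of manually selected common points; translation beyond the
common-point alignment is fixed at zero. The similarity metric is mutual
information of the joint intensity histogram over the overlap (50 bins,
full deterministic sampling). Two implementation details matter for
sub-degree accuracy and were chosen after observing angular artifacts on
known-truth phantom pairs:

* the joint histogram is Parzen-windowed — each sample spreads over the
  two adjacent bins per axis with linear weights — so the metric is
  smooth in the intensities rather than stepped at bin edges;
* the fixed volume is smoothed by half a voxel and the moving volume is
  resolution-matched (Gaussian blur at 0.5 x spacing ratio composed with
  the matching half-fixed-voxel width, then block-averaged to within 2x
  of the fixed spacing), which suppresses interpolation-induced bias of
  the metric optimum.

The pose search is staged: an exhaustive z-rotation sweep over 360
degrees at 2-degree steps (180 metric evaluations), a fine sweep over a
5-degree window — read as +/- 2.5 degrees, covering the adjacent coarse
bins — at 0.1-degree steps, then bounded quasi-Newton (L-BFGS-B, up to
2000 iterations) over the secondary in-plane angle (+/- 10 degrees) and
isotropic scale ([0.8, 1.25] of the nominal spacing ratio). Before the
quasi-Newton stage a short grid sweep seeds the scale and re-centres the
angle, and afterwards a deterministic shrinking-step coordinate polish
(steps 0.1 -> 0.025 degrees, 0.002 -> 0.0005 in scale) finishes
convergence on the shallow metric surface; if the optimised metric ever
falls below its initial value the initial transform is returned with a
warning, so the staged trace is monotone. On phantom pairs with known
transforms (z-rotation uniform over the circle, scale within +/- 5%) the
recovered rotation is typically within 0.1 degree and the scale within
0.5%.

Pseudo-labels are propagated by nearest-neighbour resampling
(`resampleLabels`; instance IDs preserved, out-of-support voxels
background) and tiled into provenance-tagged cubes
(`makePseudoCubes`). Probability maps, if resampled instead, use
trilinear interpolation followed by a 0.5 threshold.

## Morphometry

`densityMap` counts glomerular centres in a 31^3-voxel summation window
around every voxel (box convolution of the centre indicator); counts
divide by the physical window volume for a per-mm^3 field. For fully
interior centres the counts sum to exactly N x 31^3.

`zonateCortex` splits the cortex at three mean glomerular diameters from
the medulla (inner, juxtamedullary) and from the outer surface (outer,
superficial), the remainder being the mid-cortical middle zone. Distances
are Euclidean distance transforms from the medulla mask and from the
exterior region. Where the cortex is thinner than six diameters the bands
overlap and the inner zone takes precedence (a fixed, arbitrary choice);
the three masks always partition the cortex exactly. `zonalStats`
assigns instances by centroid membership, reports per-zone counts and
volume statistics (NA, never zero, for empty zones), and tests zonal
volume differences with a Kruskal-Wallis test (tie-corrected H,
chi-squared reference with k-1 degrees of freedom; an all-tied input
returns H = 0, p = 1 by convention). The mean glomerular diameter used
for zonation is twice the mean equivalent radius.

## Orchestration, determinism and problem sizes

`runCycle` executes one hierarchical cycle — training data, (optional)
preprocessing, train or fine-tune, sliding-window inference, instance
filtering, registration into the next level, pseudo-label generation —
and returns a JSON-serialisable manifest recording configs, derived
seeds, and stage metrics; `runPipeline` chains cycles down the
resolution hierarchy. All randomness flows from one root seed split per
stage by a deterministic hash (`deriveSeed`), so a rerun with the same
inputs is bit-identical. The first level refuses to run without manual
labels; later levels refuse to run without the upstream model and pseudo
cubes, naming the missing stage.

The desk-scale evaluation harnesses use phantoms of 96^3-256^3 voxels at
5-25 um/voxel: large enough that the cortex hosts a double-digit number
of glomeruli (at 9.4 per mm^3 the expected count is set by cortex
volume), small enough that the full two-level pipeline, the ten-transform
registration suite and the complete test suite each run in minutes on a
single CPU. These sizes are the package's chosen demonstration
conditions; the statistical targets (density, diameter, label fraction,
retention rates) are never adjusted per run.

## Known limitations

* The reference backbone is a linear classifier over fixed features; it
  thrives on the phantom's contrast and will not match deep networks on
  real tissue. The contract lets a heavier backbone replace it without
  touching any other stage.
* The registration model is rigid+isotropic scale about a user-supplied
  common point; deformable misalignment and common-point error are not
  modelled.
* Sphericity uses a smoothed-gradient surface-area estimate; for very
  small instances (a few voxels) it is conventionally clamped rather
  than measured.
* The phantom's intensity physics and point process are simplified;
  conclusions about real-data performance require real annotated data.
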