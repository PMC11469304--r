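---
title: "Quantifying 3D bone mineralization around the Haversian canal and the LCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D bone mineralization around the Haversian canal and the LCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

During cortical bone remodeling, osteoblasts line a resorption tunnel and
deposit unmineralized collagenous matrix (osteoid) that mineralizes after a
time lag. A forming osteon therefore shows, moving outward from the central
Haversian canal, an osteoid seam, a narrow transition zone with a steep
rise in mineral content, and mature mineralized matrix. Embedded in both
tissues runs the lacunocanalicular network (LCN): the ~300 nm canaliculi
and the lacunae that house osteocytes and their processes.

Serial FIB-SEM imaging of stained, PMMA-embedded samples produces 3D
backscattered-electron (BSE) stacks at isotropic ~40 nm voxels in which
brightness increases monotonically with local mineral content, the
embedding medium is the darkest phase, and iodine staining lifts the
unmineralized matrix above it. `mineralfront` turns such a stack plus a
co-registered compartment labeling (canal / LCN / matrix) into
distance-resolved mineralization statistics:

* a three-peak **histogram model** that classifies matrix voxels as
  unmineralized, intermediate or mineralized;
* exact 3D Euclidean **distance transforms** from the canal and from the
  LCN;
* the **gray value probability distribution** (GVPD) conditioned on
  distance, the **V~MM~/V~TM~ profile** (mineralized matrix per total
  matrix), and the **transition zone** bracketed by its 5% and 95%
  crossings;
* ring-shell statistics of the mineral-poor **halo zone** around
  canaliculi across **mineralization stages**;
* detection and morphometry of discrete **mineralization foci**.

Because raw data of this kind are rarely shareable, the package includes a
first-class synthetic phantom generator (`generate_phantom()`) with
complete ground truth; every stage of the pipeline is validated against
it.

## Segmentation model

The pooled gray-value histogram of an embedded, stained osteon has three
peaks: a sharp PMMA peak `p` at low gray values (canal and LCN porosity),
an unmineralized-matrix peak `u` and a mineralized-matrix peak `q`. With
`m` the histogram minimum between `u` and `q` and `d = q - u`, matrix
voxels are classified as

* mineralized when gray `> m + Δm`,
* unmineralized when gray `< m - Δm`,
* intermediate otherwise, with `Δm = 0.05 · d`.

The intermediate band absorbs voxels that noise and partial-volume effects
make unattributable. Intermediate voxels count in the denominator of
V~MM~/V~TM~ but never in the numerator, so a fully intermediate region has
fraction zero, not `NaN`.

Choices the histogram definition leaves open, and how this implementation
resolves them:

* Peaks and the minimum are located on a smoothed histogram (centered
  moving average, default window 5 gray levels) for noise robustness;
  peak selection is by prominence, and plateau minima resolve to the
  plateau's midpoint gray value.
* The classification thresholds use `Δm` rounded to the nearest gray
  level (gray values are integers); the model also retains the unrounded
  value.
* The threshold inequalities are strict: a gray value exactly at
  `m ± Δm` is intermediate.

Gray values are made comparable across datasets by the affine map
`Y = (X - p) / (q - p)`, anchoring the PMMA peak at 0 and the
mineralized-matrix peak at 1 (`normalize_gray()`).

When no compartment labeling is supplied, `segment_reference_compartments()`
builds one: it thresholds below the histogram minimum between `p` and `u`,
closes the dark phase (radius 1 voxel), and separates the Haversian canal
from the LCN — which are connected through the canal wall — by a
morphological opening wider than a canaliculus (`opening_radius`, default
0.25 µm): the largest eroded core touching a volume face, regrown by a
bounded dilation, is the canal; remaining dark components of at least
`min_size` voxels are LCN. Canaliculus roots within the regrowth distance
of the canal wall are absorbed into the canal; on phantoms this costs
under 1% of voxels.

## Distance-resolved statistics

`distance_transform()` computes the exact Euclidean distance from every
voxel center to the nearest reference voxel center (Felzenszwalb-
Huttenlocher separable algorithm). Distances are voxel-center to
voxel-center: relative to a sub-voxel surface definition every value
carries a systematic offset of up to half a voxel, which cancels in all
width and difference measurements used here. Transforms run on the full
volume; statistics can be restricted to an interior subvolume
(`crop_margin()`, pipeline default 1 µm) so voxels whose nearest structure
might lie outside the field do not bias canalicular statistics.

The GVPD tallies matrix voxels into half-open distance bins
`[i·w, (i+1)·w)` — `w` = 0.27 µm against the canal, 0.095 µm against the
canaliculi — and normalizes each nonempty bin to sum to one; empty bins
are flagged undefined rather than zero-filled. Moving-average gray curves
use a window of 5% of the selected voxels, reported at the window's median
distance; the class-restricted curves exclude intermediate voxels.

`detect_transition_zone()` locates the first upward crossings of 5% (the
mineralization front) and 95% on the binned V~MM~/V~TM~ profile by linear
interpolation between bin centers, after an optional 3-bin running-median
smoothing (default on) that suppresses single-bin noise; the first-crossing
rule breaks ties on noisy profiles. A profile that never reaches 95%
raises an `incomplete transition` condition carrying the front position.

## Staging and the halo zone

Tissue maturity is staged by overall V~MM~/V~TM~: stage 0 (exactly 0%),
I 5–35%, II 35–65%, III 65–95%, IV 95–99.9% and V (≥ 99.9%). Fractions
strictly between 0 and 5% have no stage in this scheme and are labelled
`UNSTAGED` rather than forced into a neighbor. `stage_subvolumes()` tiles
cuboids with a quadratic cross-section (default 8 × 8 µm², clamped with a
warning in thinner volumes) along the canal-distance direction; the radial
axis serves as the front normal, and the four in-plane directions give
replicate regions for standard errors.

`shell_profile()` evaluates V~MM~/V~TM~ in rings of width 0.095 µm
centered on given LCN distances (defaults D = 0.1, 0.25, 0.5, 2 µm),
pooling replicate regions per stage into a mean and standard error. Shells
that capture no voxels are excluded; shells with few pooled voxels are
flagged `low_support` — such cells are selection-biased (the rare voxels
far from every canaliculus cluster near a region's outer edge) and should
not enter ordering comparisons.

The halo zone — the mineral-poor sleeve around canaliculi that persists
while the surrounding tissue mineralizes — gets a width metric in
`halo_width()`: the LCN distance at which the shell profile first reaches
half of its far-field plateau (mean of shells at D ≥ 1.5 µm), linearly
interpolated, with the profile anchored at zero fraction on the
canaliculus wall. The anchoring makes the saturated limit well defined: a
profile already at plateau in its first shell returns a width below one
shell spacing (a vanished halo), while a profile that never attains half
plateau returns `NA` with a reason. Dense shell centers (one per ring
width) give the best width resolution.

## Mineralization foci

In lowly mineralized tissue, mineral first appears as discrete
sub-micrometer foci. `label_foci()` detects them as 26-connected
components of mineralized voxels (the connectivity is a convention choice;
6-connectivity is available), discards single-voxel components as noise,
and flags components touching the region-of-interest boundary as clipped.
Each focus is characterized (`analyze_foci()`) by voxel count and physical
volume, centroid, centroid distance to the nearest canaliculus, and the
V~MM~/V~TM~ of the axis-aligned 1 µm³ cube around its centroid (25 voxels
per edge at 40 nm; voxel centers inside the cube count). The local
fraction allocates the focus to group G1 (0.1–5%), G2 (5–10%) or G3
(10–20%), half-open intervals; `foci_histogram()` then builds, per group,
the distance × volume histogram in which each focus contributes weight
proportional to its volume and all cells sum to one. Boundary-clipped
foci are excluded from histograms because their volumes are truncated.

The centroid convention for the focus-to-canaliculus distance (rather
than the nearest surface voxel) is a documented choice; for sub-micrometer
near-spherical foci the two differ by at most the focus radius.

## The phantom: what it emulates and what it does not

`phantom_spec()` describes a miniature forming osteon:

* a cylindrical canal (default radius 2 µm) along one grid axis of a
  512 × 512 × 256 volume at 40 nm voxels (≈ 20 × 20 × 10 µm);
* a mineral-free osteoid seam (default 3 µm);
* a mineralized-matrix probability rising with canal-wall distance as a
  linear ramp (default width 4.078 µm), logistic curve, or step;
* straight canaliculi (default 80, radius 0.2 µm) radiating in-plane from
  the canal wall, each wrapped in a mineral-free halo sleeve whose radius
  is looked up from the *local* tissue stage and therefore shrinks as the
  front passes (defaults 0.6 µm down to 0.05 µm); sleeve radii are
  measured from the canaliculus wall;
* gray values drawn per voxel as class mean plus i.i.d. Gaussian noise
  (defaults 30/110/210 ± 6/8/8), clipped to [0, 255].

The default volume is a deliberate miniature: real osteons are an order of
magnitude larger, so lengths that would not fit (the 6–12 µm osteoid of a
real osteon, the ~25 µm canal radius) are scaled to keep the complete
transition inside the cross-section while preserving the quantities under
test, which depend on distances, not absolute size. The canaliculus count
corresponds to ≈ 0.17 µm of canaliculus length per µm³, consistent with
most bone lying within ~2.8 µm of the network.

Two mineralization modes exist. `bernoulli` draws every matrix voxel
independently with the front-profile probability — ideal for calibration
(the binned empirical fraction is binomial around the profile) but
spatially white: the speckle decorrelates between slices. `foci` places
rasterized spheres by a Poisson point process whose intensity reproduces
the same expected fraction; spheres span several slices, which makes this
mode the right fixture for registration tests, and its realized fraction
falls slightly below the target as coverage saturates (sphere overlap), so
it is used at low fractions. Foci never rasterize into halo sleeves, the
osteoid, or non-matrix voxels.

Geometry, mineral placement and gray noise draw from three independent
sub-streams of one seed, so artifacts can be toggled without changing the
geometry, and a fixed spec is bit-reproducible.

Deliberately not modeled: curved canaliculi (straight ones keep the
distance ground truth analytic and preserve every tested statistic),
lacunae as distinct ellipsoids, lamellar contrast, collagen texture, and
BSE physics. Passing tests on phantoms therefore demonstrates the
correctness of the computations and the recoverability of known
parameters, not robustness to every property of real tissue.

`add_artifacts()` emulates the three stack pathologies of serial surface
imaging — cumulative per-slice lateral drift (rounded to whole voxels),
curtaining stripes constant along the milling direction, and extra
Gaussian noise — and returns the applied shift sequence as alignment
ground truth.

## Preprocessing operators

`align_stack()` estimates inter-slice displacement by zero-mean circular
FFT cross-correlation at integer resolution, accumulates it into a drift
trajectory, and resamples each slice by the negative trajectory after
subtracting its rounded mean: relative displacements are corrected
exactly, and the stack is recentered rather than pinned to the first
slice (the returned trace keeps the first-slice-zero convention; the
applied integer corrections ride along as an attribute). Featureless
slice pairs warn and carry zero displacement. Sub-voxel refinement is
deliberately out of scope: slices are resampled by whole voxels, so
estimates are integer by construction.

`destripe()` removes per-slice column residuals against a running-median
baseline (default window 15 voxels): stripes narrower than about half the
window are rejected entirely, while coherent structure — which a running
median follows through steps and wide dips — survives. One caveat follows
from the method, not the implementation: random per-column composition
fluctuations (e.g., a Bernoulli transition zone exactly one voxel thick
in the stripe direction) are formally identical to stripes and are
removed with them.

`denoise()` offers a 3D box median or a separable Gaussian. A median of
radius 1 suppresses isolated single-voxel speckle by design — appropriate
for imaging noise, destructive for single-voxel structure, which is why
the pipeline leaves denoising off by default and the foci minimum size is
2 voxels.

## Numerical and validation choices

* Histogram smoothing window 5 gray levels; destripe window 15 voxels;
  alignment search radius 10 voxels — all configurable.
* Transition crossings: linear interpolation, first-crossing rule, 3-bin
  median pre-smoothing.
* Monotonicity checks across stages compare pooled shell fractions with a
  two-standard-error binomial allowance and exclude thinly supported
  shells: the generator's output is a random sample, so exact ordering
  holds only in expectation.
* Validation problem sizes: unit tests run phantoms of 48³–240×240×80
  voxels; transition-zone recovery uses five 352 × 352 × 64 phantoms in
  the test suite and five full 512 × 512 × 256 phantoms in the
  acceptance script; distance transforms and component labeling are
  checked exactly against exhaustive-search and flood-fill oracles on
  volumes up to 25³. These sizes are the package's validation design:
  large enough that binomial noise sits well inside the tolerances being
  checked, small enough to iterate on.

## Known limitations

* Compartments must be co-registered; no elastic registration is offered.
* The automatic canal/LCN separation absorbs canaliculus roots near the
  canal wall into the canal and cannot split lacunae from canaliculi
  (both are "LCN").
* Anisotropic voxels, geodesic distances and signed interior distances
  are out of scope.
* Foci tracking over time and sub-voxel focus shape analysis are not
  attempted; the stage axis is a space-for-time reading of a single
  volume, not a time series.

## A minimal session

```{r example}
library(mineralfront)

ph <- generate_phantom(phantom_spec(seed = 1))
model <- fit_histogram_model(ph$volume, ph$truth$compartments)
classes <- classify_matrix(ph$volume, ph$truth$compartments, model)

d_canal <- distance_transform(ph$truth$compartments, COMP_HAVERSIAN)
profile <- mineral_profile(classes, d_canal, bin_width = 0.27)
detect_transition_zone(profile)

d_lcn <- distance_transform(ph$truth$compartments, COMP_LCN)
regions <- stage_subvolumes(classes, d_canal)
shells <- shell_profile(classes, d_lcn, regions)
plot_shell_profile(shells)
```

The same analysis runs end to end from files via `run_pipeline()` with a
`pipeline_config()` (or a YAML file through `read_config()`), writing all
products as CSV with units in their headers plus a YAML run manifest.
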