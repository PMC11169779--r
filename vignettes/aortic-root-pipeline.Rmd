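---
title: "Aortic-root segmentation post-processing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic-root segmentation post-processing: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaseg)
```

# The problem

Pre-procedural planning for transcatheter aortic valve replacement
(TAVR) needs a labelled model of the aortic root from contrast CT
angiography: the ascending aorta (AA), the left ventricle (LV), the
valve leaflets, and calcification. Automated pipelines obtain the
labels from a trained segmentation network; everything that happens
*after* that network is classical, testable computation, and that is
what this package implements: geometric preprocessing, cleanup of the
predicted label volume, determination of the number of valve cusps,
tricuspid/bicuspid classification with Sievers subtyping (type 0 = no
raphe, type 1 = one raphe), anatomical leaflet naming, and a
segmentation-quality metric suite. The network itself is deliberately
out of scope — the pipeline sees segmentation as a pluggable contract
(`ImageVolume -> LabelVolume` on the same geometry), and a
deterministic threshold-based `reference_segmenter()` stands in for it
on synthetic data. It is a stand-in for testing the downstream stages,
not a claim of equivalence with a learned model.

# Coordinate and container conventions

Volumes are dense 3-D arrays with per-axis voxel spacing in mm, an
origin, and an RAS-like axis convention (+x right, +y anterior, +z
superior). Voxel `(i, j, k)` (1-based) has its *centre* at
`origin + (c(i,j,k) - 1) * spacing`. All distances are computed between
voxel centres in world millimetres. Label volumes carry the fixed
vocabulary 0 background / 1 AA / 2 LV / 3 leaflet / 4 calcification and
are geometrically congruent with their paired image; every geometric
operation preserves that congruence, and tests assert it.

# Preprocessing

* **Resampling.** Images are interpolated trilinearly onto an isotropic
  grid (default 0.5 mm), labels by nearest neighbour, with voxel
  centres aligned and the half-voxel origin shift handled explicitly:
  the output grid covers the same world extent (within one voxel) and
  the output shape is `round(extent / target)`. Resampling an already
  isotropic-at-target volume reproduces it to < 1e-6. Nearest-neighbour
  ties at the exact half-voxel boundary round half-up; the test-suite
  oracle uses the same stated convention.
* **Intensity.** Values are clipped to [0, 1200] HU and then mapped
  affinely to [0, 1]. Clipping precedes normalization because the clip
  thresholds are HU quantities; applying them after normalization would
  be dimensionally incoherent.
* **Cropping and patches.** `crop_to_body()` returns the tight bounding
  box of supra-threshold voxels plus a fixed 2-voxel margin together
  with the offset, so paired volumes can be cropped congruently.
  `extract_patch()` cuts an `edge^3` cube centred on a voxel,
  zero-padding outside the volume.
* **Augmentation.** One rigid rotation (each axis limited to ±20°) and
  one isotropic zoom (0.85–1.15) are applied identically to image
  (trilinear) and labels (nearest), about the volume centre in world
  coordinates; noise and artifacts are then added to the image only.
  Out-of-range parameters are rejected rather than clamped. Every
  stochastic operation is a pure function of its seed. The out-of-field
  fill is 0 HU, the lower clip bound.

# Determining the number of cusps

The leaflet voxels' world coordinates are clustered with seeded
K-means (10 restarts, Lloyd iterations) at k = 2 and k = 3. Full-batch
K-means is used rather than a mini-batch variant: at desk scale (one to
a few thousand leaflet voxels) mini-batching saves nothing and only
adds variance.

**Choosing between k = 2 and k = 3.** The obvious criterion — the mean
silhouette coefficient of each partition — turns out to be weak
exactly where it matters. Cusps are thin curved wedges; for a bicuspid
valve the two cusps are long arcs, and splitting one arc in half
produces clusters about as silhouette-compact as the true two-cluster
partition. Measured on phantoms, the silhouette margin between the
correct k = 2 and the wrong k = 3 is a few hundredths and occasionally
inverts. The package therefore decides with a criterion that uses what
silhouettes ignore, the *spatial* gap structure: for each candidate
partition it computes the **boundary-cut fraction** — the fraction of
leaflet voxels with a 26-neighbour assigned to a different cluster.
When k is correct, K-means boundaries fall inside the commissural gaps
and the fraction is essentially zero; when k is wrong, at least one
boundary must cut through a continuous cusp sheet and the fraction
rises to several percent. The smaller fraction wins. When the two
fractions are indistinguishable (difference < `cut_tol`, default 0.01
— e.g. a pathological single-blob mask), the mean silhouette decides,
and a silhouette tie (< `tie_tol`, default 0.005) goes to k = 3, the
prevalent tricuspid morphology. Silhouettes for both k are always
computed (on a seeded subsample of at most 1500 voxels, shared between
the candidates, to bound the all-pairs distance cost) and reported.

**Refinement.** The K-means partition is then polished with a
K-nearest-neighbour vote: voxels in the boundary band (those with a
disagreeing 26-neighbour, dilated by one voxel) are re-labelled by the
majority of their `n_neighbors` (default 15, odd) nearest leaflet
voxels outside the band, in world coordinates; tied votes go to the
lower cluster index. The voxel set itself never changes — refinement
only repartitions it.

# Valve classification and the raphe detector

Three clusters mean a tricuspid valve. Two clusters mean a bicuspid
valve, and the Sievers subtype hinges on whether a raphe — the fibrous
ridge marking congenital fusion of two cusps — is present. Since
nothing in a label volume marks the raphe explicitly, the package uses
a geometric detector built around how a raphe presents: a ridge
standing proud of the leaflet surface, running radially from the
free-edge region toward the wall at a fixed angular position on the
conjoint cusp.

The detector expresses the leaflet cloud in its own principal frame
(the sheet normal is the smallest principal axis, which makes the
procedure rotation-invariant), removes the radial height profile
shared by the cusp surfaces (median height per radial bin), and
integrates the remaining height residuals per 10° angular bin as the
mean excess over `resid_floor_mm` (1.2 mm, about two-thirds of the
leaflet thickness), smoothed over three adjacent bins. A raphe is
declared when the peak window carries at least `peak_min_mm` (0.10 mm)
of evidence, dominates the angular background by at least `peak_ratio`
(3×), and its ridge voxels span at least 35% of the valve radius.
These gates were calibrated on phantom cohorts to keep the
false-positive rate on raphe-free valves at zero while tolerating the
erosion that segmentation inflicts on the thin ridge; under heavy
degradation the detector fails toward *missing* the raphe, so
classification errors concentrate in the type-1 → type-0 cell — the
same error mode reported for clinical pipelines, where type-1 valves
with subtle raphes resemble type-0 valves.

# Leaflet naming

The valve's long axis is estimated from the AA and LV centroids
(pointing LV → AA, i.e. superior), cluster centroids are projected onto
the annular plane, and angles are measured from +x (right) toward +y
(anterior). For three cusps the canonical centre angles are
right-coronary 90°, left-coronary 210°, non-coronary 330°, and names
are assigned by the permutation minimizing total angular discrepancy —
so each name is used exactly once and the labelling is stable under
modest axial rotation (the test suite checks ±10°). For two cusps the
more anterior centroid is "anterior". True coronary-ostium-based naming
would need ostia labels, which the vocabulary does not contain; the
angular convention is the documented approximation.

# Segmentation metrics

Overlap: `DSC = 2|P∩G|/(|P|+|G|)`, `precision = |P∩G|/|P|`,
`recall = |P∩G|/|G|`. Distances: surfaces are the mask voxels with at
least one face-adjacent (6-neighbourhood) voxel outside the mask, the
grid edge counting as outside; nearest-surface distances are pooled
over both directions; `hd95` is their 95th percentile (R's default
type-7 quantile; a `variant = "max"` flag gives the classical Hausdorff
distance) and `assd` their mean, both in mm, voxel-centre to
voxel-centre. Degenerate inputs follow total-evaluation conventions:
two empty masks agree perfectly (DSC 1, flagged); one empty mask makes
the undefined ratios 0 (flagged) and distances NA; `evaluate_case()`
marks structures absent from both volumes rather than zeroing them.
Implementations are verified against an all-pairs brute-force oracle to
1e-9 on random masks.

The composite loss `λ·(1 − softDice) + (1−λ)·focal` (defaults λ = 0.5,
γ = 2, α = 0.25; the training literature's usual values, since no
specific setting is prescribed) is provided as a standalone scalar:
soft Dice is averaged over classes (empty classes count as perfect) and
the focal term clamps the true-class probability to [1e-7, 1 − 1e-7] so
a perfect one-hot prediction yields a loss of numerically zero, and the
uniform two-class prediction with γ = 0, α = 1 reduces to the
cross-entropy ln 2.

# The phantom generator

`generate_phantom()` builds, from a `phantom_spec`, a paired
image/label volume: an aortic tube of annulus radius *R* (default
12 mm, a typical annulus) standing on an annular plane; an LV made of
an ellipsoid body plus a cylindrical outflow tract of annular caliber
reaching the plane, so the leaflets rest on blood as they do on the
real LVOT; 2 or 3 cup-shaped leaflet sheets
(`z(r) = z0 + depth·(1 − (r/R)^2)`, thickness 1.8 mm) spanning angular
sectors separated by constant-width commissural gap bands whose width
at the wall is set by `cusp_gap_deg` (default 14°, i.e. ≈ 2.9 mm ≥ 2
voxels everywhere, which guarantees the cusp-count-by-components
invariant); a central coaptation hole kept minimal, as closed leaflets
meet centrally; for type-1 valves a thin raphe fin on the conjoint
cusp rising ≈ 3.5 mm above the sheet from 0.25 R to the wall; and
non-overlapping calcific nodules placed on the sheets away from gaps
and raphe. Pre-noise intensities are blood 400 HU, leaflet 150 HU,
calcification 1000 HU, background −50 HU — inside the [0, 1200] HU
clip window and ordered so leaflets are the lowest-contrast class, as
they are in practice. Everything is a pure function of the spec;
cohorts derive per-case seeds and ±10% geometric jitter from a single
seed.

What the phantom does *not* emulate: sinuses of Valsalva, coronary
ostia, the aortic wall as a distinct intensity, partial-volume
blurring of the noiseless palette, cardiac motion, contrast gradients,
or beam-hardening. Consequently, passing tests demonstrate the
correctness and robustness of the *post-segmentation* computations
under controlled degradation — they do not certify performance of any
segmentation network on patient data.

`degrade_image()` adds seeded Gaussian noise (σ on the normalized
scale, i.e. σ·1200 HU) and, optionally, low-frequency cosine bias
fields plus two planar streaks as an artifact model; artifacts are
additive and geometry-preserving.

# The reference segmenter

A deterministic stand-in for the learned stage, tuned to the phantom
palette on the normalized scale: band thresholds at the class-midpoint
intensities (leaflet band [0.065, 0.235), blood [0.235, 0.58),
calcification ≥ 0.58); an optional edge-preserving 3×3×3 median filter,
triggered when a robust noise estimate (MAD of adjacent-voxel
differences over non-clipped foreground) exceeds 0.015 — a Gaussian
blur would erase the thin leaflet sheets; leaflet candidates restricted
to the interior of the morphologically closed blood pool, which
separates true leaflets (slits inside the pool) from the
partial-volume shell where the pool meets background; the blood pool
split into AA and LV at the basal leaflet plane along its principal
axis, oriented so the wider (ventricular) side lies below; and
scattered-piece cleanup. On noiseless phantoms this recovers the
palette nearly exactly, which is what makes the end-to-end acceptance
run a test of the downstream stages rather than of the segmenter.

# Post-processing of predicted labels

Scattered-piece removal keeps the single largest connected component
for AA and LV (ties broken toward the component containing the
lexicographically smallest voxel index), but *not* for leaflets and
calcification: those structures are legitimately multi-component (2–3
sheets, many nodules), and strict largest-component filtering would
delete true anatomy. They instead lose components below a small size
floor (20 voxels / 2% of foreground for leaflets, 3 voxels for
calcification). Component analysis defaults to 26-connectivity because
thin oblique sheets fragment under 6-connectivity.

# Determinism, problem sizes and error handling

All randomness flows through explicit integer seeds (`withr::with_seed`
keeps the global RNG untouched); identical configuration and seeds
yield byte-identical reports, which the tests assert by comparing
serialized CSV/JSON. The pipeline isolates failures per case: a case
whose leaflet mask is empty is reported failed with its error message
while the rest of the cohort proceeds.

The cohort sizes exercised by the tests and the acceptance script —
64³-voxel phantoms at 0.7 mm spacing, 60-case recovery and robustness
cohorts, 10-case end-to-end runs, 50 random mask pairs against the
brute-force oracle — were chosen as the smallest sizes at which each
property is meaningfully exercised (thin sheets several voxels thick,
balanced three-class cohorts, surface sets in the hundreds), keeping
the whole suite comfortably fast on a single CPU.

# Known limitations

* The cuspid-number stage assumes the leaflet mask is dominated by the
  valve; large far-field false positives would distort the clustering.
  The pipeline mitigates this with size filtering and the pool-interior
  restriction, not with anatomical priors.
* The raphe detector is calibrated on this phantom family; its absolute
  thresholds (mm-scale evidence gates) would need re-calibration for
  data with different leaflet thickness or resolution, and Sievers
  type 2 (two raphes) is outside the class vocabulary altogether.
* Leaflet naming uses a fixed angular convention, not coronary ostia.
* The reference segmenter is palette-specific by design and is not a
  general CTA segmenter.
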