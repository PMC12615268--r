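---
title: "Consensus 3D segmentation from orthogonal 2D views: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus 3D segmentation from orthogonal 2D views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoseg3d)
```

## The problem and the model

Microscopy volumes are usually segmented slice by slice, because 2D
instance segmenters are far better trained than 3D ones. The hard part is
aggregation: 2D cell IDs carry no identity across slices or across the
three orthogonal view directions, slices of one 3D object may split into
several 2D regions (any branched shape), and per-slice errors (missing,
split, merged masks) must be out-voted rather than propagated.

`orthoseg3d` aggregates in a continuous representation instead of
matching discrete IDs. Each 2D cell is encoded by (i) its binary support
and (ii) the unit gradient field of a distance transform Φ computed on
its own footprint. The key geometric fact is that the medial-axis
transform of a 3D object is consistent with the medial axes of its 2D
slices: eroding every foreground point along its 2D-derived gradients,
after fusing them into a 3D field, gathers the points of one object onto
one spatially compact attractor, which is detectable by proximity alone —
no cross-slice correspondence needed. Reversing the erosion (every point
remembers where it started) turns attractor IDs into a 3D label volume.

### Distance transforms

Six transforms are available per 2D cell, differing in where erosion
stops and how smooth the flow is:

* `edt` — Euclidean distance to the background; implicit attractor (the
  2D medial axis). Fast and the default.
* `poisson` — solve ∇²Φ = −1 with Φ = 0 on the first background pixel
  (5-point stencil, sparse LU per cell on its padded bounding box);
  a smoother, curvature-penalised erosion, same implicit attractor.
* `poisson_point` / `poisson_skeleton` — Laplace's equation with a unit
  source at a chosen interior point / on the 2D skeleton; the source set
  attains the interior maximum, so all mass contracts to it. The point
  variant admits a power transform (Φ − Φ_min)^p (default p = 1).
* `geodesic_point` / `geodesic_skeleton` — travel time from the source
  set restricted to the mask, computed by multi-source Dijkstra on the
  8-neighbour pixel graph with Euclidean edge weights. This is a
  first-order approximation to the Eikonal solution; its metrication
  error (the 8-neighbour metric overestimates distances by up to ~8% off
  the lattice directions) is documented and acceptable because only the
  gradient *direction* drives descent. Gradients on source pixels are
  zeroed to enforce the limiting behaviour.

The interior point source is the foreground pixel nearest the
coordinate-wise median among pixels whose EDT exceeds the 10th
percentile — inside the mask even for crescents. Skeletons are computed
by iterative thinning after Gaussian pre-smoothing (σ = 3) and
mean-thresholding, which suppresses spurious boundary branches. Masks of
one or two pixels use the EDT path for every explicit variant (their
source systems degenerate); the implicit Poisson solve is well posed down
to a single pixel (4Φ = 1).

One sign convention is fixed at the field level: **stored fields always
point toward the attractor**, and descent adds η·field. Geodesic (source-
minimum) transforms use masked, one-sided differences at the cell
boundary — the travel time is undefined outside the mask, and naive
central differences would point the boundary ring outward, stranding
trajectories in the zero-field exterior.

### Fusion

Views are fused voxel-wise by the content-based average
F = Σᵢ wᵢ Iᵢ / (Σᵢ wᵢ + ε), wᵢ = 1/(σ_N^i + α), where σ_N is the local
standard deviation over a P³ window (population estimator, symmetric edge
padding — the estimator and edge rule are our fixed choices), α = 0.5 is a
pseudo-count and ε = 1e−20 only guards the division. P = 1 makes F the
plain mean (used for gradients); P = 3 (used for the foreground) lets
locally consistent views out-vote slice dropouts. Each 3D gradient
component is fused from the two views that observe it; with fewer views,
unobserved components start at zero and are imputed only by the σ_post
smoothing. Fields are pre-smoothed per 2D slice (σ_pre = 1, preserving
view independence), post-smoothed in 3D (σ_post = 1) and unit-normalised
on the foreground support. Larger σ_post regularises — it merges nearby
attractors and prevents over-segmentation, at the risk of merging small
true cells.

The foreground binarisation threshold is 0.5 (majority vote) for binary
mask inputs; probability inputs use multi-class Otsu on the fused map
(2-class by default; 3-class with the lower threshold when segmentation
is too conservative, the higher when too liberal), floored at 0.25 so an
empty image cannot hallucinate foreground, with optional round-down to
one decimal.

### Suppressed descent and clustering

The update for point n at iteration t is

x ← x − η (δ·∇Φ(xₜ₋₁) + μ·∇Φ(xₜ₋₂)) / (δ + μ),  η = δ/(1 + tτ)

with nearest-voxel (rounded) field sampling, positions kept as floats and
clipped to the volume every step. Defaults: T = 250, δ = 1, μ = 0.95,
τ = 0. The decay τ is the one knob adjusted per morphotype: elongated and
branched shapes fragment if points travel too far, so τ = 0.5 suits
convex packings and τ = 2 thin networks. The missing history at the first
step is taken as zero (the first step is scaled by δ/(δ+μ)); this
convention is covered by a regression test. Points sitting on zero
gradients stay put and are handled by clustering.

Final positions are floored onto the grid, counted, and smoothed with a
Gaussian (σ = 1) into a density ρ; attractors are the connected
components (26-connectivity) of ρ > mean(ρ) + k·std(ρ). We default to
k = 0 — the working setting for all in-package results — and expose k = 1
as the conservative alternative, since both conventions are in
circulation. Each starting voxel inherits the attractor ID at its final
position; points landing below threshold stay background and are counted,
never silently reassigned, because silent relabelling would mask gradient
errors. With T = 0 the routine returns connected components of B exactly,
implemented as an explicit branch because the density path would only
approximate that identity.

For large volumes, descent runs per subvolume tile (default 25% overlap);
each voxel is advected in the single tile whose Voronoi core owns it,
clipped to the tile, and globalised by adding the tile offset. The
overlap must exceed a cell's attractor basin radius for tiled ≡ untiled
equality, which the tests assert on two-sphere fixtures.

### Postprocessing

The recommended chain is: remove cells < 200 voxels and reduce every
label to its largest connected component; remove cells whose recomputed
own-mask field disagrees with the descent field (per-cell mean absolute
per-component error > 0.85, a threshold calibrated for σ_post = 1 — note
that two *independent* random unit fields have expected error 2/3, so
this filter targets cells grossly inconsistent with their own geometry,
not merely noisy ones); remove cells larger than mean + 5·sd of cell
volumes (with strict inequality, so equal volumes are never culled — and
note a single outlier among n cells can only be detected when √n > k);
then, given a guide image (a blend α·I_norm + (1−α)·I_ridge of the
normalised image and its Hessian ridge enhancement), refine by label
diffusion and guided filtering.

Label diffusion one-hot encodes labels in a padded crop (pad 25) and
iterates z ← (1−γ)Az + γL for T = 25 steps on an affinity matrix blending
intensity similarity exp(−D²/2·mean(D)²) with plain adjacency
(6-neighbour by default; the 8-neighbour phrasing of 2D label spreading
is ambiguous in 3D, so 26 is exposed as an option). We row-normalise A so
the iteration is a contraction — without normalisation z grows without
bound; this is our addition and is flagged here. The default mode treats
each cell independently as binary against a background source; a joint
multi-label mode lets all cells compete (only there can two seeds split a
corridor at its midline). γ = 1 or T = 0 is the identity by construction.

The guided filter computes the standard local linear model a = cov(I,p)/
(var(I)+ε), b = p̄ − a·Ī over a cubic box window of half-width r = 35
(box means via separable uniform filters), feathers the mask as
q = ā·I + b̄, and rebinarises by two-class Otsu; other cells' voxels are
masked out. r bounds the protrusion length that can be recovered; very
large ε degrades gracefully to an Otsu'd box blur of the mask. A single
pass is applied; iterating for very long protrusions is left to callers.

### Evaluation

Predicted and reference cells are matched one-to-one by minimising
1 − IoU (Hungarian algorithm over the dense IoU matrix when both sides
have ≤ 50 cells, otherwise candidates are each predicted cell's 10
nearest reference centroids), keeping only overlapping pairs. Both label
images are first relabelled sequentially after a stable centroid sort, so
results are invariant to ID permutation. AP = TP/(TP+FP+FN) and
F1 = 2TP/(2TP+FP+FN) are reported over 11 IoU thresholds equisampling
[0.5, 1]. Two empty images score 1 (no objects, no errors); one-sided
emptiness scores 0. For references that only label part of the field of
view, predicted cells can be restricted to predicted-foreground
components overlapping the reference foreground by ≥ 25% (≥ 1% for thin
vessel data).

## The synthetic generator: what it emulates and what it does not

The generator spans the morphotype spectrum the method must handle:
`convex` packs non-overlapping digital spheres (voxel centre within
radius; placement by rejection with a 2-voxel minimum gap, a bounded
number of retries, and an explicit placement-failure error); `branched`
builds objects of 2–5 tube segments meeting at a junction, oriented so
in-plane slices near the fork split into multiple 2D regions; `network`
grows random trees of radius 1–3 tubes (nearest-earlier-node attachment,
one tree per disjoint subregion). Slicing treats each contiguous in-plane
region of a single 3D label as one 2D cell (8-connectivity, per source
label, so touching objects stay distinct 2D cells), and the corruption
model applies drop → split → merge → jitter per slice in a fixed order
under one seed.

Passing on these fixtures demonstrates the aggregation machinery —
reconstruction, separation of touching objects, fragment containment,
view symmetry — under ideal and controlled-corruption inputs. It does not
demonstrate robustness to real 2D segmenter errors (systematic biases,
texture-dependent failures), anisotropic point-spread functions, or
intensity statistics of real microscopy; no photorealistic simulation is
attempted. Morphotype parameters (sphere radii 7–11 voxels at 96³,
tube radii 4–6, network radii 1–3) are calibration choices giving objects
comfortably above the 200-voxel QC floor at desk-scale volumes, not
values taken from any dataset.

## Numerical choices and degenerate inputs

* Axis order is (z, y, x) everywhere; view xy slices along z, xz along y,
  yz along x; 0-based voxel coordinates at unit-cube centres.
* Gaussian and box filters are separable with symmetric (reflect)
  padding; kernels truncate at 4σ.
* Nearest-voxel sampling during descent uses rounding; flooring is
  reserved for the final rasterisation.
* Unit normalisation guards 0/0 with a 1e−12 magnitude floor — flat field
  regions give exact zero vectors.
* The Φ = 0 Dirichlet ring sits on the first background pixel, so Φ > 0
  on all foreground.
* Constant images are rejected by percentile normalisation and Otsu
  (undefined scaling) rather than silently passed through.
* Label TIFFs are stored as 16-bit integer pages (bit-exact up to 65535
  labels); intensity TIFFs as 32-bit float in [0, 1].
* Axis-permutation symmetry of the whole pipeline is asserted voxel-exact
  on generator fixtures; the fused fields agree across permutations to
  ~1e−16 (floating-point pass ordering), which does not flip any label on
  the tested fixtures.

## Problem sizes

In-package tests and the reproduction script run at desk scale: 96³
fixtures with 4–8 objects for reconstruction checks, 48³–64³ for unit
properties, 100 randomized trials for the matching oracle, T = 150–250
descent iterations. These sizes were chosen so every property is
measurable in seconds while objects remain large relative to voxel
discretisation; the pipeline itself is size-independent and the tiled
descent path is the intended route for volumes that do not fit the
single-block path comfortably.

## Known limitations

* The geodesic solver is graph-based Dijkstra, not fast marching; exact
  travel times differ by the 8-neighbour metrication factor.
* Per-cell binary label diffusion cannot grow a cell into unlabelled
  territory against the clamped background prior; use the joint mode (or
  lower γ) when boundary relocation matters.
* The gradient-consistency filter cannot flag cells whose field errors
  are *correlated* with their geometry; its threshold semantics assume
  σ_post = 1.
* Single-view reconstruction imputes the unobserved gradient component
  only through smoothing; coaxially stacked objects along the missing
  axes will merge.
* Direct mode trusts the predictor's gradient convention (pointing toward
  cell centres); fields with the opposite sign must be negated upstream.
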