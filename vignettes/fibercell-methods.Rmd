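---
title: "Fiber segmentation, morphometry and cell-fiber spatial analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber segmentation, morphometry and cell-fiber spatial analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercell)
```

# Scope and model

`fibercell` treats a stained-tissue image as a superposition of bright
curvilinear fibers on a darker background, and a tissue section as two
object populations — cells (segmented and classified elsewhere, imported
as a table) and fibers (extracted here) — living in one pixel coordinate
frame. The package answers two kinds of questions: *what does each fiber
look like* (six per-fiber features) and *what surrounds each cell or
fiber* (neighborhood counts, aggregated neighbor-fiber features, and
nearest-object distances).

The fiber model is deliberately simple: a fiber is one connected
foreground component reduced to a single branch-free curve. Fibers that
cross or touch therefore merge into one object. This is a modeling
choice, not an accident: resolving crossings requires fiber *tracking*
(nucleation points extended through intersections, as in curvelet- or
tracking-based tools), a different algorithm family with a much higher
computational cost. Users quantifying densely interwoven networks should
read the fiber count as a count of fiber *bundles*.

## Coordinate and intensity conventions

All coordinates are 0-based pixels: `x` is the column index increasing
rightward, `y` the row index increasing downward, in every table, mask
and skeleton the package reads or writes. Angles are measured against
the +x axis in the Cartesian sense — the raster y axis is flipped before
`atan2` — and folded into [0°, 180°) because fibers are undirected. The
convention is declared (rather than inferred) and locked by tests: a
chord from (y=0, x=0) to (y=100, x=100) has angle 135°.

Intensities are kept on the 0–255 scale so the intensity feature has a
fixed meaning across inputs: 8-bit data pass through untouched; 16-bit
and floating-point data are linearly min–max rescaled to 0–255 (a
constant image maps to 0). PNG data, normalized to [0, 1] by the reader,
are multiplied by 255.

# Fiber extraction

## Foreground separation

Two methods are built in, selectable per run:

* **Simple/Otsu thresholding** (`threshold_simple`): pixels ≥ a fixed
  value, or the Otsu value computed on the 0–255 histogram. Effective
  for sparse fibers on a clean background.
* **Frangi vesselness** (`threshold_frangi`): multiscale Hessian ridge
  detection for dense, net-like fiber fields. At each scale σ the
  image is convolved with σ²-normalized Gaussian second-derivative
  kernels; with Hessian eigenvalues |λ₁| ≤ |λ₂| the response is
  V = exp(−R_b²/2β²)·(1 − exp(−S²/2c²)), R_b = λ₁/λ₂,
  S = √(λ₁²+λ₂²), restricted to λ₂ < 0 (bright ridges). β = 0.5 is the
  standard blob-sensitivity choice; c is set per scale to half the
  maximal Frobenius norm, which adapts the structureness term to image
  contrast. The response is maximized over scales, min–max normalized
  per image, and cut at a user threshold (default 0.15). Default scales
  {1, 2, 3} px match fiber half-widths of roughly 1–3 px; set them to
  the half-widths you expect.

A precomputed binary mask can be supplied instead (`foreground`
argument / `--method mask`), supporting workflows where separation is
done in other software.

## Labeling, thinning, pruning

Connected components are labeled at 8-connectivity by default — thin
diagonal fibers fragment under 4-connectivity — and components smaller
than `min_size_px` (default 20 px) are discarded as debris. The default
debris thresholds (`min_size_px = 20`, `min_fiber_length_px = 10`) are
the smallest structures we consider fibers rather than speckle at
typical magnifications; both are configurable.

Each component is thinned to a 1-px skeleton with the **Guo–Hall**
two-subiteration algorithm. We initially used Zhang–Suen thinning and
found it completely annihilates some even-width diagonal strokes (a
documented flaw of that scheme); Guo–Hall handles every orientation ×
width combination we render (0–170° × 2–8 px) without fragmenting or
erasing. Should thinning ever erase a tiny blob entirely, its innermost
pixel (maximal distance transform) is kept so every labeled component
yields a skeleton.

Thinning leaves spurs and branch points wherever the mask bulges.
**Pruning** reduces the skeleton to a single branch-free curve, defined
as the longest geodesic path through the skeleton's pixel graph
(8-neighbor edges, weight 1 orthogonal / √2 diagonal). Any cycles left
by thinning artifacts are first broken by a maximum-weight spanning
tree, so the path runs along the longer side of an artifact loop. Among
equal-length longest paths the one whose start endpoint is smallest in
(y, x) lexicographic order (then smallest end) is chosen, making output
deterministic. This global longest-path formulation — rather than
iterative spike clipping — realizes "remove all side branches" in one
deterministic step, and is validated against a brute-force
all-pairs-geodesic oracle on random pixel trees.

One digitization artifact remains after exact pruning: the longest
geodesic may gain ≈√2 by wrapping a 1-px spur at a fiber tip, ending
with a step that reverses direction. `trim_path_hooks()` removes such
backtracking terminal pixels (negative dot product between successive
steps). An 8-connected rasterization of a smooth curve turns at most 45°
per step, so genuine fiber shape is never trimmed. `segment_fibers`
applies the trim; `prune_to_longest_path` itself stays the exact
geodesic so its oracle contract is preserved.

Fibers whose pruned curve is shorter than `min_fiber_length_px` are
dropped and the mask relabeled consecutively, keeping mask and skeleton
list mutually consistent.

# Per-fiber features

**Length** is the curve length between the two endpoints, measured on
the skeleton path resampled every 5 pixels (endpoints always kept) with
Euclidean chords summed. Raw chain-code length (1/√2 per step)
overestimates digitized oblique lines by up to ~8% — a 30° digital line
of true length 100 has chain length ≈ 107.7 — while resampling reduces
the error to a fraction of a percent and remains *exact* on horizontal,
vertical and 45° paths (collinear resampling points). The 5-px stride is
small enough that fibers curving on realistic scales (radius ≫ 5 px)
lose under 0.5% of arc length.

**Thickness** is the mean, over skeleton pixels, of the Euclidean
distance transform of the fiber's mask component — the distance from the
medial line to the outline, i.e. the half-width. Because "width" is the
more common quantity in the fiber-morphometry literature, the table also
carries `width_px = 2·thickness_px`.

**Straightness** is chord/curve, L/l ∈ [0, 1]. Note the inverse ratio
l/L is ≥ 1 by the triangle inequality; we use the orientation of the
ratio that matches the stated [0, 1] range and the name (1 = straight).

**Alignment** of fiber *i* is mean(cos αⱼ) over the fibers *j* whose
reference point (skeleton centroid by default) lies within
`alignment_radius_px` of fiber *i*'s; αⱼ is the orientation difference
folded into [0°, 90°], so cos αⱼ ∈ [0, 1]: 1 for a locally parallel
field, 0 for a perpendicular neighbor. Two closed-form limits anchor the
scale: a fully parallel field scores exactly 1, and an isotropic field
scores E[cos α] = 2/π ≈ 0.637 (α uniform on [0°, 90°]). A fiber with no
neighbors in the radius gets a *missing* alignment — never 0, which is a
legal value meaning "perpendicular neighborhood". The alignment radius
is an independent configuration key from the spatial-analysis radius;
the two measure different things (fiber-field order vs cell
neighborhoods) even when set equal.

Features undefined on degenerate fibers (coincident endpoints,
zero-length curves) are emitted as missing values throughout.

# Spatial analysis

Cells and fibers are merged into one object table keyed by (kind, id),
so numeric ids may collide across kinds without ambiguity. The
neighborhood "outline" parameter is a **radius** in pixels (a µm radius
is converted via `pixel_size_um` and refuses to run without it).
Membership uses the closed disc — an object at distance exactly r
counts. An object never counts itself. Counts are exact: the
implementation is a vectorized full distance computation, tested for
bit-identity against exhaustive double loops on randomized scenes, and
is monotone in the radius by construction.

Nearest-object distances (`nearest_distance`) break ties by the
smallest target id; an empty target class yields a missing value, never
0 or an error. Objects closer to the image border than the radius get a
`near_border` flag; their outlines are truncated and no edge correction
is applied — consumers can filter on the flag.

Profile clustering uses Ward linkage (`ward.D2`) on Euclidean distances
over z-scored features. Aggregate columns can be missing (a cell with
zero neighboring fibers has no mean neighbor-fiber length); those
entries are set to 0 *after* standardization and accompanied by a 0/1
presence column, so "has no fibers nearby" acts as information rather
than being imputed to the population mean.

# The synthetic generator

`render_scene` draws parametric curves — straight segments, sinusoids,
circular arcs — stroked to a given width (distance-to-curve ≤ w/2, round
caps) with a flat or Gaussian cross-profile, composed by maximum onto a
constant background, plus additive Gaussian noise clipped to [0, 255]
and quantized to 8 bit. Ground truth is analytic-first: arc lengths come
from closed forms (straight, arc) or adaptive quadrature of the
parametric speed to 10⁻¹⁰ relative tolerance (sinusoid), and the exact
rasterized footprint of every fiber is recorded. `place_straight_fibers`
guarantees disjoint fibers by capsule-distance rejection sampling, so
planted counts are exact. All randomness flows through one seeded
generator; regeneration is bit-stable.

Default study conditions used by the validation suite: background 20,
peak 200, noise σ = 15 (SNR ≈ 12 at the stroke, comfortably above the
SNR ≥ 5 regime where thresholding is reliable), fiber widths 3–6 px and
lengths 40–90 px on 512²–900² images — magnitudes typical of collagen
fibers in the 1920 × 1440 px tissue images this kind of pipeline
targets. What the generator does *not* emulate: optical blur (an
optional Gaussian profile approximates soft edges, but there is no PSF),
background texture and staining heterogeneity, fiber crossings in the
validation scenes (crossing behavior is tested separately as a
documented merge), and out-of-focus structures. Passing the recovery
suite therefore demonstrates correctness of the algorithms under the
stated image model, not robustness to every artifact of real stains.

## Validation design and problem sizes

The validation quantities recomputed by `scripts/acceptance.R` (and
asserted by the test suite) are: exact fiber-count recovery on 20 seeded
scenes per N ∈ {5, 10, 20, 50}; length/angle/thickness/straightness
recovery on the 3 × 3 × 6 straight-fiber grid (L ∈ {50, 100, 200} px,
w ∈ {3, 5, 7} px, θ ∈ {0…150°}) within tolerances |Δl| ≤ 0.05·L + 4 px
(the additive term allows for end erosion by thinning), |Δθ| ≤ 3°,
|Δthickness| ≤ 1 px, straightness ≥ 0.97; closed-form limits (rendered
semicircle straightness 2/π ± 0.03, exact 10√2 diagonal, parallel
field = 1, isotropic 2500-fiber field 2/π ± 0.02); equality of pruning
with a Floyd–Warshall geodesic oracle on 200 random ≤ 60-node pixel
trees; bit-identity of spatial queries with exhaustive scans on 20
seeded 500 × 500-object scenes; ≥ 95% planted-region recovery by Ward
clustering of tumor-cell profiles; and byte-identical artifacts across
two end-to-end runs. These sizes keep the whole suite within a few
minutes on one CPU while leaving each property statistically meaningful.

# Numerical choices and degenerate inputs

* Thresholding uses ≥, so a fiber at exactly the threshold value is
  foreground.
* The Frangi response of an exactly constant image is defined as zero
  (FFT round-off would otherwise manufacture ridges out of noise at
  machine epsilon).
* Empty inputs are contracts, not errors: an empty mask labels to zero
  components, a blank image segments to an empty fiber list, an empty
  fiber table writes a header-only CSV.
* A single-pixel skeleton is a degenerate path of length 0, flagged,
  and filtered by the minimum-length rule in the pipeline.
* Ties everywhere are broken lexicographically (pruning endpoints) or
  by smallest id (nearest distances), for determinism; cluster labels
  come from `stats::hclust`, whose merge order is deterministic for a
  given input.
* Pipeline runs are end-to-end deterministic for fixed config and
  inputs; the run manifest records inputs, configuration and package
  version (no timestamps), so a manifest plus the repository reproduces
  a run byte-identically.

# Known limitations

* Crossing/touching fibers are one object (see above); counts in dense
  networks are bundle counts.
* Thickness is the medial half-width; for fibers near 1 px wide the
  distance transform saturates at 1, so sub-pixel widths are not
  resolved.
* The alignment feature depends on the chosen reference point
  (centroid); for strongly curved fibers the centroid can sit off the
  fiber body. A skeleton-distance mode for spatial queries is available
  for that case.
* Neighborhood counts near the image border are truncated, flagged and
  uncorrected.
* Processing is per-image and single-threaded; determinism is
  guaranteed, image-level parallelism is left to the caller's job
  runner.
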