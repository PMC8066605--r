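---
title: "Profiling the diameter of tubular structures in 2D images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the diameter of tubular structures in 2D images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubewidth)
```

## The problem and the model

A biological tube photographed against a contrasting background — a vessel
segment, a fallopian tube on a light table — is, for measurement purposes,
a ribbon whose two bounding edges wander across the image and whose
calibre varies continuously along its length. `tubewidth` treats diameter
estimation as a geometry-recovery problem in three parts: find the two
edges, reconstruct the solid silhouette between them, and measure the
silhouette's thickness along the normal of its centreline at every point.
The method makes three standing assumptions, inherited from the imaging
setup it targets:

* the tube's extremities run off the image (or the tube is entirely
  enclosed), so exactly two long, continuous edges bound it;
* the tube is photographed roughly in-plane — out-of-plane bending makes
  pixels an inconsistent unit and is not corrected;
* one tube per image; touching clutter (ligaments, shadows) is handled
  only insofar as its edges are shorter than the tube's.

The output is a per-index record: centreline position, local tangent
slope, the two contour points hit by the normal rays, and their Euclidean
separation $d_i$ — the local diameter — in pixels and optionally in
millimetres.

## Pipeline stages and the parameters that matter

### Pre-processing

Greyscale conversion averages the channels (weights are exposed for
vessels over-represented in one channel). A normalised discrete Gaussian
(`sigma`, default 2 px; radius `ceiling(3*sigma)`) suppresses the pixel
noise that would otherwise fragment the gradient ridge along an edge.
Borders are padded by reflection about the edge sample (reflect-101), so
no artificial frame gradient is created: for validation phantoms whose
tube is cut by the frame, this means the cut itself produces *no* edge —
which is what keeps the detected edge count at exactly two.

The contrast stage defaults to the linear stretch to the full 8-bit range,
which is order- and shape-preserving and exactly the identity on images
that already span 0–255. Histogram equalisation is available
(`use_equalization = TRUE`) and is the right choice for murky photographs
with compressed dynamic range; it is *not* the default because on
high-contrast imagery it is actively harmful: equalisation reallocates
output levels in proportion to pixel counts, so on a near-binary image
nearly the whole output range is spent crossing the two dominant
intensity masses, and the steepest part of the remapped edge ramp — where
the gradient detector will fire — moves from the physical boundary to the
last step before the dominant bright level, several pixels inside the
brighter region. On the straight validation phantom this relocates both
edges inward by ~5 px each and biases the measured width from ~100.2 px
to ~89.5 px. The package therefore treats equalisation as an opt-in
enhancement for low-contrast inputs, not as a default stage.

### Edge detection

The gradient operator is the 3×3 pair with centre weight 3 and outer
weight 2 (a slightly flatter variant of the classical 1-2-1 Sobel;
`sobel_kernel = "classical"` switches to the textbook kernels for
comparison — on the phantoms the difference is imperceptible). Gradient
orientation is quantised to {0°, 45°, 90°, 135°} buckets and non-maximum
suppression compares each pixel with its two neighbours *along* the
gradient; the comparison is `>=`, so a plateau of equal magnitudes
survives rather than being erased — relevant for perfectly grid-aligned
edges, whose smoothed profile is symmetric and peaks on two pixels at
once.

Hysteresis thresholds are specified as fractions of the peak suppressed
magnitude (`z2_frac = 0.20`, `z1_frac = 0.08`) so that the same
configuration works regardless of a given image's absolute contrast. Weak
pixels (between the thresholds) are kept exactly when a path of non-zero
pixels connects them to a strong pixel; the scan is a deterministic
breadth-first search — reachability does not depend on visit order, so a
randomised scan would decide identically. Of the surviving 8-connected
components only the two longest are kept; when clutter defeats that
heuristic, `manual_edge_indices` overrides the choice explicitly.

### Silhouette filling

Each column is filled between its first and last edge pixel, then each row
likewise, and the silhouette is the **intersection** of the two passes
(`fill_combination = "union"` is available for comparison). Intersection
is the right combination because each single pass fills the scan-line
convex hull: on an oblique or curved tube one direction overshoots
precisely where the other is tight.

The subtlety is scan lines that do not see both edges. Detections in a
scan line are clustered (gaps of more than 3 px separate clusters); a line
with two well-separated clusters carries both edges; a single cluster is
assigned to one edge trace by continuity with neighbouring lines. Because
an edge crossing can drift many pixels per scan line when the edge runs
nearly parallel to the scan direction, continuity is judged with a
freshness rule: a trace updated in the last couple of scan lines claims a
cluster within a drift tolerance (12 px per line of age) in preference to
a trace that has been silent for many lines — otherwise an edge sweeping
past the other edge's long-stale position would be mis-assigned. Interior
runs where a trace is missing (detection gaps) are interpolated with one
Bresenham segment between the flanking detections; leading/trailing
missing runs are clamped to the image border when the nearest detection
sits against that border (the edge has left the image scope), and carried
from the nearest detection otherwise. On straight-edge phantoms with
punched gaps of median length 1 px, the filled boundary deviates from the
gap-free fill by at most ±1.5 px — the accuracy limit of linear
interpolation under this gap model.

### Centreline extraction

Zhang–Suen thinning (two sub-iterations, iterated to a fixed point;
implemented in C++) reduces the silhouette to a connected skeleton, but
one that is locally too thick to index: diagonal staircases keep doubled
pixels whose neighbour counts reach 3–4. The secondary thinning enforces
the "at most two neighbours" property needed for a one-dimensional
coordinate list. Its deletion test asks whether a pixel's 1-valued
neighbours remain a single 8-connected cluster without it; note that the
classic ring-transition count is the wrong test under 8-adjacency (the
North and West ring neighbours touch diagonally even when the NW corner is
empty), which is why the test is computed on true adjacency. Two
supplementary rules complete it: corner pixels of "triangles" (a
two-neighbour pixel whose neighbours touch each other and are themselves
overcrowded) are redundant and deleted; and if genuine junctions remain
(short spurs off the main line), the shortest endpoint-to-junction branch
is pruned. The result is asserted on every pipeline run: no remaining
pixel has more than two neighbours.

The ordered line is walked endpoint-to-endpoint (the endpoint with the
smaller row-major coordinate is index 1; closed loops start at their
smallest row-major pixel). Diagnostic only — it does not feed back into
the pipeline — `concentricity_check()` reports the half-difference of the
two normal ray lengths per index, i.e. how far the thinned line sits from
the true mid-position; on the phantoms it stays below a pixel over the
valid domain.

Zhang–Suen's sub-iterations have a directional preference, so the skeleton
of a mirrored image is *not* the pixel-exact mirror of the skeleton; the
measured diameters are nonetheless orientation-stable (the tests assert
mean-diameter invariance within 1 px under mirroring, 90° rotation and
translation), which is the form of orientation-unbiasedness that matters
for the measurement.

### Width measurement

The local slope at index $i$ uses the symmetric finite difference with a
±4-index stencil (`gradient_offset`): wide enough to average the ±1 px
jitter of a rasterised line (a digitised slope-2 line is recovered within
0.15), local enough to track curvature; near the line ends the stencil
shrinks symmetrically. Vertical tangents are flagged explicitly (`Inf`)
and the normal handled as exactly horizontal, never through a floating
overflow. Rays are integer Bresenham walks (ties of the minor coordinate
round half-up in the driving frame), terminated at the last silhouette
pixel before background or at the frame border; no sub-pixel refinement is
attempted — the validation accuracy statement is in whole pixels.

`end_trim` (default 75 indices per end, chosen at the 500-px frame scale
and meant to be scaled with the image) excludes the end regions where
thinning initiation and rays truncated by the frame distort the
measurement; summaries are reported over both the full range and the
valid domain so the end-noise is visible rather than hidden.

## What the synthetic phantoms do and do not show

The generator renders anti-alias-free, maximal-contrast phantoms with
analytic ground truth: straight bands of perpendicular width 100 px at a
10° incline, annulus arcs (outer radius 500 px, radial width 100 px)
centred on the frame corner, both polarities, varying-width tubes with a
prescribed width function, and a resolution-rescaled variant in which all
lengths scale with the frame (width too — otherwise relative accuracy
would improve trivially with size). A pixel is foreground exactly when its
centre satisfies the analytic inclusion test; the truth table stores the
width at integer arclengths. Degradation is seeded and reproducible:
punched edge gaps with geometric lengths (median 1 px; gaps are interior
to an edge by construction — removing an edge's *end* is truncation, a
different failure mode with no flanking data to interpolate from) and
optional Gaussian intensity noise with a background ramp.

On these phantoms the pipeline achieves: every interior index of the
straight tube within 1 px of truth; arc means of 100.11 px against true
100 (the validation bands are 100.1 ± 0.5 and 99.9 ± 0.5 for the two
polarities); arc mean absolute error 0.39 px; 0.12% mean error at the
1500-px rendering; ≤ 1 px filled-edge deviation under gap degradation;
and 0.61 px RMSE recovering a sinusoidally varying width. These numbers
certify the geometry engine, not field performance: real photographs add
intensity noise, uneven illumination, soft (blurred) edges, attached
clutter and calibration error, none of which the binary-contrast phantoms
exhibit. The noise/gradient degradations probe robustness in that
direction but are not a tissue model.

## Numerical choices and degenerate inputs

* Intensity remaps round half-up, once per stage (with a 1e-9 epsilon
  absorbing binary representation error of decimal scale factors).
* All coordinates are 1-based `(row, column)`, row axis downward; profile
  indices are 1-based. Serialised outputs follow the same convention.
* Orientation quantisation assigns interval endpoints (22.5°, 67.5°, …)
  to the higher bucket, deterministically; the neighbourhood is labelled
  P2…P9 clockwise from North, which places every quantisation triple
  along the gradient axis.
* Constant images cannot be stretched (warned, returned unchanged) and
  yield zero gradients everywhere, which surfaces as the
  too-few-edge-components error with a hint to adjust thresholds.
* A tube narrower than ~2 px thins to a line whose rays terminate
  immediately (d ≈ 0); widths below the smoothing scale are not
  meaningfully measurable.
* The default path contains no randomness: identical input and
  configuration produce byte-identical profile CSVs.

## Problem sizes used in the test-suite

The bundled validation runs the full pipeline on 500×500 phantoms
(sub-second each) and one 1500×1500 rendering (~11 s), 50 gap-degradation
replicates, and property suites (hysteresis vs. brute-force reachability
on 200 random maps, thinning vs. an independent reference on 50 random
blobs, rasterisation vs. a midpoint-algorithm oracle on 500 segment
pairs). The whole suite completes in well under a minute on one core.

## Known limitations

Single tube per image; global (not adaptive) thresholding, so strong
background intensity ramps near the tube degrade edge selection — the
equalisation flag or manual edge override are the levers there; external
contour only (no lumen measurement); no out-of-plane correction; 2D only.
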