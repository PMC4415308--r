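---
title: "Measuring wound geometry against a virtual healthy skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wound geometry against a virtual healthy skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundmetrics)
```

## The measurement problem

Chronic-wound healing is monitored through the wound's perimeter, area and
volume. A single-view triangulation scanner delivers a colored 2.5D height
field of the wound and its surroundings, but none of the three quantities is
well defined without a reference: the volume of a cavity only exists
relative to the surface that *intact* skin would form across it. The package
therefore constructs a **virtual healthy skin** (ViHS) — a smooth spline
surface anchored around the wound and approximated to the surrounding
healthy skin — and measures everything against it.

```r
g   <- synth_generate(synthetic_wound_spec(seed = 1))
res <- analyze(g$wounded, g$true_mask, wound_config(seed = 1))
summary(res)
```

## Pipeline and model

**Input.** An `organized_surface`: a `rows x cols` lattice with per-cell 3D
point (mm) and 8-bit RGB. Column index maps to physical x, row to y, z
points toward the scanner; wounds are low-z regions. Invalid cells (no
return from the scanner) carry `NA`. The format assumes a height field —
overhanging geometry cannot be represented, which matches what a
single-view scan can see in the first place.

**Edge detection.** Segmentation runs on the aligned color image. All three
back-ends take their operator input as files/arguments, never
interactively, so studies are scriptable:

* `segment_ced()` — Canny with Gaussian pre-smoothing (`sigma = 1.4` px,
  the common default), hysteresis thresholds relative to the maximum
  gradient magnitude, morphological closing, optional manual stroke
  polylines, and straight-segment bridging of residual gaps up to
  `gap_max = 10` px. The enclosed interior (flood fill from the border on
  the edge-map complement) is the mask.
* `segment_growcut()` — cellular automaton on the 8-neighborhood with
  attack strength `g(d) = 1 - d/d_max`, `d_max = 255*sqrt(3)`. Seeds start
  at strength 1 and can never be conquered (a candidate's strength is
  strictly below 1), so seed labels are invariant. Updates are synchronous
  with a fixed neighbor order, hence bit-reproducible.
* `segment_grabcut()` — iterative foreground extraction: 5-component
  full-covariance Gaussian mixtures for wound/background, re-estimated
  against the current partition, alternating with an s–t min cut
  (contrast-adaptive 8-neighbor smoothness, `gamma = 50`). Seeded pixels
  are contracted into the terminals, which keeps the cut graph small and
  enforces the hard constraints exactly. The k-means initialization is
  seeded from the config, so reruns are identical.

Every back-end ends the same way: keep the largest 4-connected component,
fill interior holes, and restrict to valid cells. Hole filling means
islands of intact-looking tissue inside the wound count as wound — the
single-outer-contour convention; the alternative (subtracting islands)
would need a multi-contour edge model and is deliberately out of scope.

**Edge metrology.** A contour traced through pixel centers (Moore-neighbor
tracing) carries two systematic errors: staircase excess in its length, and
a half-pixel inward offset, because the path runs through the centers of the
outermost foreground pixels. Before measurement the traced contour is
therefore resampled, smoothed with a circular Gaussian (`smooth_sigma_px =
2` vertex steps), and offset outward along the normals by half the grid
pitch. On rasterized ellipses of realistic size this brings perimeter and
enclosed-area errors below about 0.3% (raw traced contours are off by
several percent). Edges supplied analytically (not traced from a mask) are
used verbatim.

**ViHS.** `min_area_rect()` circumscribes the minimal-area rectangle to the
edge via the convex hull (one side of the optimum is always hull-edge
collinear), fixing the orientation of the ViHS reproducibly to the wound
itself. The spline domain is this rectangle expanded outward by `margin_mm
= 5` along its own axes: the rectangle is tangent to the wound edge, so
without the margin its boundary would run through wound tissue at the
tangency points, and an inward-scattered vertex could clip the wound out of
the domain. The surface is a non-rational tensor-product cubic B-spline
(`n_ctrl = 8` per direction, open-uniform knots, unit weights) in `z` over
a bilinear `(u,v) -> (x,y)` map of the domain quad:

1. boundary curves: the measured z sampled along each domain edge
   (wound/invalid samples replaced by arc-length interpolation from
   flanking healthy samples; an edge with no healthy sample at all aborts
   the instance), fitted by clamped cubic B-splines with corner heights
   shared between adjacent edges;
2. interior initialization: discrete Coons patch of the four boundary
   curves on the Greville abscissae;
3. refinement: penalized least squares of the interior control points
   against all healthy valid cells inside the domain (`lambda = 0.1`,
   skipped below `min_samples = 50` cells).

The penalty is a thin-plate-style quadratic form built from *divided*
differences on the physically scaled Greville positions. Two details
matter: divided (not raw) differences make the penalty vanish exactly on
affine control nets, so planes are reproduced to machine precision even at
the clamped ends where knot spacing is non-uniform; and the physical
scaling makes `lambda` independent of the domain size (a raw-parameter
penalty grows quadratically with the quad and was observed to flatten the
fit visibly). Inside the wound, where no data exist, the penalty alone
propagates the surrounding curvature; because minimizing squared second
differences with matched boundary values and slopes reproduces quadratics,
cylinder-like skin is bridged with errors well below 0.1 mm RMS for
curvature radii of tens of millimeters.

**Scattering.** `scatter_quads()` displaces each rectangle vertex
independently and uniformly within a `5 x 5` mm square (half-width 2.5 mm)
aligned with the rectangle's own axes — alignment keeps the ensemble
geometry invariant under rotation of the wound; the global-frame
alternative would make results orientation-dependent. Self-intersecting
draws are redrawn. One master seed drives everything, so the 31-instance
ensemble is bit-reproducible; `half_width = 0` collapses it to 31 identical
surfaces (a property the tests assert).

**Metrics.** `deviation_field()` evaluates both surfaces on a global
lattice at `h = 0.25` mm (the scale of the scanner's stated accuracy; all
instances share cell positions, so in-wound classification is computed once
per analysis). The parameter map is inverted by vectorized Newton iteration
(tolerance 1e-9, divergence at more than 1% of interior cells aborts the
field). Deviation is measured along the scan z axis, not the ViHS normal:
a height field makes the z-prism decomposition exact and the integral
well-defined; for strongly overhanging virtual skin the normal-based
integral would differ, a documented limitation. `integrate_vdw()` sums
positive and negative prisms separately and reports
`vdw = v_pos + |v_neg|` — an exact identity, asserted per instance.
Perimeter and area are evaluated *on the ViHS* (edge densified to `h`,
lifted; area elements with the metric factor), which is what makes
averaging them across the 31 instances meaningful; a `frame = "measured"`
config switch evaluates them on the measured surface instead, for
comparison with planimetric conventions.

**Aggregation.** Means and sample (n−1) standard deviations over surviving
instances; instances whose fit fails are dropped with a warning, and an
analysis with fewer than half its instances aborts.

## The synthetic generator and what it shows

`synthetic_wound_spec()` emulates a lower-leg scan: a cylinder (radius
~55–70 mm) with a sinusoidal undulation, i.i.d. Gaussian range noise
(default sd 0.05 mm, about a fifth of the scanner-accuracy scale, shared
between the wounded and healthy outputs so they agree exactly outside the
wound), and an elliptical wound carved with a cosine-taper or
super-Gaussian depth profile that reaches zero exactly on the ellipse
boundary. Texture is two noisy colors blended across the rim. Ground truth
comes from `oracle_truth()` — brute-force quadrature at `pitch/8` on the
*noise-free* base, sharing no code with the measurement path (dense
boundary polyline for perimeter, analytic base gradients for area
elements, depth-times-cell-area for volume; 2x refinement moves each value
by <0.2%). Truth on the noise-free base means measured-vs-expected
differences include a realistic noise contribution, as a bias experiment
should.

`standard_suite()` fixes six wounds in three before/after pairs (shallow,
deep/steep-walled, irregular on a strongly undulating base), depths
2.5–6 mm and oracle volumes ≈500–2700 mm³, matching the scale of modeled
verification wounds for such scanners. The defaults — 0.25 mm pitch, 31
instances, 5 × 5 mm scatter — are the study conditions; at these settings
the mean absolute relative measurement differences on the suite are a few
tenths of a percent.

What the generator does *not* emulate: laser speckle, occlusion shadows,
specular skin highlights, motion during the ~5 s acquisition, or the
ambiguous, low-contrast edges of real shallow wounds. Passing the suite
therefore demonstrates the correctness and numerical accuracy of the
geometry pipeline under realistic noise — not segmentation performance on
difficult clinical imagery, which in practice is the dominant error source
and the reason the operator stays in the loop.

## Numerical choices and degenerate inputs

* Integration step `h = 0.25` mm: halving it changes VDW by <0.5% on all
  suite wounds (asserted); the cost grows quadratically.
* Hysteresis thresholds are relative to the maximum gradient magnitude; a
  border band is excluded from that maximum (padding artifacts).
* Ties in GrowCut conquests resolve by fixed neighbor order; GrabCut
  k-means by the seeded RNG — both for determinism.
* Collinear edges, empty masks, missing seed classes, unclosed Canny
  contours, underconstrained ViHS fits and empty deviation fields raise
  classed conditions (`wm_degenerate_geometry`, `wm_empty_mask`,
  `wm_seed_missing`, `wm_edge_not_closed`, `wm_vihs_underconstrained`,
  `wm_empty_wound`), mapped to distinct exit codes by the CLI.
* `resample_to_grid()` uses inverse-distance-weighted local *plane* fits
  (moving least squares) rather than plain weighted means: at realistic
  densities the plain mean's bias/variance exceeds the 0.05 mm target on
  curved surfaces, while the plane fit is exact on tilted planes.
* Repeatability reporting uses Levene's test (mean-centered) and the
  one-way Kruskal–Wallis test at the conventional 95% confidence level;
  all-constant input short-circuits to p = 1 (no evidence of any kind).

## Problem sizes

Tests and the bias experiment run on surfaces up to ~260 × 240 cells
(64 × 60 mm at 0.25 mm pitch); a full 31-instance analysis of one such
wound takes a few seconds on one CPU, the six-wound suite well under a
minute. These sizes were chosen as the smallest that keep all length scales
(wound, scatter square, margin, spline span) in their realistic ratios.

## Known limitations

* 2.5D only: undercut wound walls are integrated as seen from the scanner.
* One wound per analysis (largest component); multiple wounds need
  multiple runs.
* Interior healthy islands are counted as wound (hole filling).
* Area/perimeter are ViHS-referenced by default; planimetric studies may
  prefer `frame = "measured"`.
* The GrabCut color models assume the wound is colorimetrically coherent;
  heavily mixed fibrin/granulation/necrosis may need generous seeds.
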