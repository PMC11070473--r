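---
title: "Measuring stem diameter from RGB-D imagery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stem diameter from RGB-D imagery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemdepth)
```

## The measurement problem

Stem diameter at the second internode is a standard maize phenotype tied to
lodging resistance and yield. Calipers are accurate but slow and invasive;
`stemdepth` implements a non-contact alternative: a side-view RGB-D camera
(an active-stereo device producing a colour image, a registered depth
raster and a point cloud) observes the stem, and the diameter is recovered
as the 3-D Euclidean distance between the two silhouette edges of the stem
at a scanline, using the sensor's own depth and the pinhole camera model.
No reference object (checkerboard) is needed at measurement time, which is
the method's practical advantage over ground-sample-distance scaling.

The pipeline, in order:

1. **Alignment.** The depth raster lives on the depth sensor's grid;
   `align_depth_to_color()` deprojects every valid depth pixel, moves it
   through the depth-to-colour extrinsics and reprojects it onto the colour
   grid, keeping the nearest surface per target pixel (z-buffer). Holes are
   left visible (value 0) rather than interpolated: invented depth would
   silently bias the chord.
2. **Segmentation.** `hsv_otsu_segment()` gates pixels to a green hue range
   (default 35–85° on the 0–360° scale) and applies Otsu's
   between-class-variance threshold to the saturation channel inside that
   gate. The hue gate supplies the colour prior (green stem vs soil); Otsu
   adapts the saturation split to the scene's illumination. `denoise()`
   (5×5 majority-vote median, then a 3×3 cross-shaped opening) and
   `largest_component()` (8-connected) reduce the mask to the single
   dominant stem.
3. **Contour and centreline.** `internal_gradient_contour()` returns
   `mask − erode(mask)`, the inner boundary. `thin()` is a two-subiteration
   thinning: sub-step A deletes simultaneously every boundary pixel with
   2 ≤ N ≤ 6 foreground neighbours, exactly one 0→1 transition around the
   clockwise neighbour ring, and north·east·south = east·south·west = 0;
   sub-step B uses the mirrored conditions north·east·west =
   north·south·west = 0. Iterated to its fixed point this leaves a
   one-pixel centreline that is a subset of the mask, idempotent, and
   connectivity-preserving.
4. **Scanlines.** Within a row region of interest (the second internode;
   config-driven, by default a fractional band of the stem's bounding box),
   `skeleton_points_in_roi()` picks `n_scanlines = 3` evenly spaced
   centreline points; `scanline_intersections()` walks each row outward to
   the nearest contour pixel on each side.
5. **Back-projection and frame mapping.** Both edge pixels are
   back-projected with the colour intrinsics and a *shared* depth (see
   below): `Z = d`, `X = (x−c_x)/f_x·Z`, `Y = (y−c_y)/f_y·Z`. The points
   are then flipped from the image-processing convention (x right, y down,
   z forward) into the point-cloud convention of the colour stream
   (`flip_yz()`, negating y and z) and carried into the depth-stream frame
   by the rigid extrinsic transform `p' = R p + t`. Because rigid maps and
   the axis flip are isometries, the chord length is identical in every
   frame; the package asserts this to 10⁻⁹ mm on each measurement.
6. **Diameter.** `1000·√(Δx²+Δy²+Δz²)` mm per scanline; the stem's value is
   the **median** of its scanlines. The median is used because the field
   protocol repeats the extraction three times for consistency without
   stating a combiner, and the median is robust to a single contour defect.

`pinhole_baseline()` implements the comparison method: stem pixel width
scaled by a checkerboard's mm-per-pixel factor at a reference plane. It
exists to reproduce the published method comparison, not as a product
feature; its error grows with the stem-to-board depth offset, which the
depth-based method does not suffer from.

## Which depth feeds the back-projection

Depth at a silhouette edge pixel is unreliable on stereo sensors: it
straddles the stem/background boundary and frequently reads background or
is invalid. The package therefore uses the aligned depth at the *centreline*
point for both edge pixels (falling back to the median of valid depths in a
5×5 window). Geometrically this measures the chord at the stem's *front
surface* depth `Z − R` rather than at the tangent-point depth, which
underestimates the diameter by a factor `(Z−R)/√(Z²−R²)` ≈ `1 − R/Z`
(about 2% at the design geometry of a 25 mm stem at 0.6 m). This bias is a
property of the published procedure and is deliberately left uncorrected;
the synthetic experiments quantify it.

## Subpixel edge convention

A mask boundary pixel's centre sits, on average, half a pixel inside the
continuous silhouette, so a chord between pixel centres systematically
loses one pixel of width — worth 1 px · Z/f, i.e. 1–4% of a maize stem's
diameter at field ranges. `measure_at_scanline()` therefore displaces the
edge pixels half a pixel outward (`edge_offset_px = 0.5`) before
back-projection, spanning the outer edges of the two boundary-pixel
footprints. This is the standard unbiased subpixel reading of a binary
boundary; setting `edge_offset_px = 0` restores raw pixel centres. The
residual discretisation error is zero-mean with magnitude below one pixel
and is further damped by the three-scanline median.

## Coordinate-frame bookkeeping

Three frames appear: the OpenCV-style image frame of the colour camera
(y down, z forward), the colour stream's point-cloud frame (y up, z toward
the viewer) and the depth stream's point-cloud frame, where the exported
PLY cloud lives. Every 3-D point carries a mandatory frame tag
(`point3()`), and `flip_yz()` / `rigid_transform()` check and rewrite the
tags, so a frame mix-up is a hard error rather than a silent sign flip.
Camera configs state the depth↔colour extrinsics between the point-cloud
frames; `align_depth_to_color()`, which works on back-projected (image
convention) points, conjugates them with `D = diag(1, −1, −1)` (`R → DRD`,
`t → Dt`) so that alignment and the measurement choreography are mutually
consistent and annotated coordinates land on the point cloud.

With the shared centre-depth rule the annotated edge markers sit slightly
off the true surface — about 0.4·R radially outward at the limb — so
`annotate_pointcloud()`'s recolouring radius should be of the order of the
stem radius when the markers are meant to highlight surface vertices.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hue_range` | (35, 85) | degrees | green vegetation against soil; configurable for other crops |
| `median_ksize` / `open_ksize` | 5 / 3 | px | smallest kernels that remove field speckle without eroding a ≥15 px stem |
| connectivity | 8 | — | consistent with the thinning neighbourhood |
| `roi` | 0.55–0.80 | fraction of stem bbox height | stand-in for the second internode when no annotation exists |
| `n_scanlines` | 3 | — | the field protocol's three repeats |
| `edge_offset_px` | 0.5 | px | subpixel footprint correction (above) |
| depth fallback window | 5×5 | px | median of valid depths when the centre pixel is a hole |
| `depth_scale` | 0.001 | m/unit | millimetre depth units, 16-bit range covers 65 m |
| `prune` | 0 (off) | passes | endpoint peeling for leaf-stub skeleton branches; opt-in |

Border handling for all local filters is reflection, so filters never erode
the raster edge. Otsu ties break to the smallest level; a single-valued
gated histogram keeps the whole hue gate (there is nothing to split).

## The synthetic scene generator

Field captures cannot be reproduced at a desk, so `render_scene()` builds
the geometry the rig saw: a right circular cylinder of known radius at
0.4–1 m, viewed against a farther fronto-parallel background, rendered
analytically (per-pixel ray/cylinder intersection) in both the depth and
colour cameras of a realistic 848×480 model with a ~15 mm stereo baseline.
Ground truth — diameter, silhouette, per-row widths, projected axis, and
the visible-surface point cloud — comes from the same closed-form geometry,
and renders are bit-reproducible from the scene specification and seed. Optional depth
degradation: integer quantisation (always representative of real sensors)
and i.i.d. Gaussian noise.

`fixture_suite()` fixes the study conditions: 20 scenes on an even grid
over diameters 17–41 mm (the span of the field tables), distances
0.45–0.9 m, and axis tilts 0–30°, each at depth-noise 0 and 2 mm. Tilt is
realised chiefly as pitch toward the camera — the dominant effect of the
rig's 45° downward view of a near-vertical stem — with in-image-plane
components up to 10°. The in-plane cap is deliberate: a horizontal scanline
across a stem tilted by angle θ *in the image* measures a chord inflated by
1/cos θ, and a stem 30° off vertical in the frame is outside the method's
operating envelope; field maize is near-vertical in side view.

What the generator does *not* emulate — leaves and occlusion, illumination
variation, wind motion, elliptical stem cross-sections (an ellipse mode
would only change the chord by the axis ratio), stereo-correlated depth
noise — bounds what a passing suite shows: the geometry, image-processing
and bookkeeping chain is correct under clean conditions at realistic scale
and quantisation; field robustness is a property of the capture protocol,
not of this code.

On this suite the full pipeline's mean absolute percentage error is ~2.1%
noiseless and essentially unchanged at 2 mm depth noise (the chord depends
on depth only through the centre sample, so 2 mm at 0.6 m is a 0.3%
perturbation) — the same scale as the 3.01% the field study reports, with
the residual dominated by the uncorrected centre-depth chord bias.

## The evaluation suite

`stem_metrics()` reproduces the published analysis on paired
(method, caliper) vectors: MAPE, MAE, RMSE; the *residual* R²
`1 − Σ(k−w)²/Σ(k−k̄)²` (not a fitted regression's R²); Lin's concordance
`ρ_c = 2ρσ_xσ_y / (σ_x² + σ_y² + (μ_x−μ_y)²)` with population (1/n)
moments — with n = 60 the sample-moment variant differs below the printed
precision; and a two-sided Wilcoxon signed-rank test, zero differences
dropped, normal approximation with tie-corrected variance and continuity
correction by default (the published variant is unspecified; an exact mode
for small tie-free samples, and full 2ⁿ enumeration under ties, are
provided). Box-plot summaries use type-7 (linear interpolation) quantiles,
configurable because quartile conventions differ between tools; the
packaged tables' printed medians reproduce under type 7, while the printed
interquartile ranges and "distribution widths" do not match max−min or any
standard quantile type and are reported, not asserted.

The two 60-plant field tables ship as plain CSV (`stem_tables()`); all of
their printed aggregate statistics are recomputed by the test suite and by
`scripts/acceptance.R` at printed precision.

## Numerical and degenerate-input policy

* Pixels are 0-based `(col, row)` with the centre at integer coordinates,
  matching the intrinsics convention; rasters are R matrices indexed
  `[row+1, col+1]`.
* Invalid depth is 0; alignment never writes a zero for a valid splat.
* Back-projection refuses non-positive depth and out-of-bounds pixels;
  projection refuses points behind the camera; `extrinsics()` validates
  orthonormality and determinant to 10⁻⁹.
* Scanlines missing a contour side, or without valid depth near the
  centre, are skipped and logged per scanline; the stem fails only when
  every scanline does, with the per-scanline reasons in the error.
* Empty masks, empty ROIs, all-zero histograms and empty manifests raise
  classed conditions (`stemdepth_*`) rather than producing silent zeros.
* Depth persists as lossless 16-bit single-channel TIFF (the installed PNG
  writer is 8-bit only; 16-bit PNG is still read), point clouds as PLY 1.0
  ascii or binary-little-endian, camera configs as JSON/YAML with
  17-significant-digit doubles so round-trips are bit-exact.

## Problem sizes

The shipped experiments are sized for a desk machine: the synthetic suite
is 20 scenes × 2 noise levels at the full 848×480 sensor resolution
(about a minute end to end), module tests use a 320×240 camera, and the
oracle comparisons run on 28×36-pixel random blobs and n ≤ 12 sign
enumerations, where brute force is exact and fast.

## Known limitations

* One dominant stem per frame; no multi-stem scene logic.
* The centre-depth chord bias (~R/Z) is inherent to the published
  procedure and uncorrected.
* Strictly horizontal scanlines inflate the chord by 1/cos(in-plane tilt);
  a perpendicular-to-axis mode is not enabled by default to stay faithful
  to the published procedure.
* The second-internode ROI is supplied by configuration, not detected.
* No lens distortion model (undistorted pinholes throughout).
* Learning-based segmentation and live camera capture are out of scope.
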