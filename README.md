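# stemdepth

Non-invasive maize stem diameter measurement from RGB-D imagery, in R.

Stem diameter at the second internode predicts lodging resistance and
biomass in maize, but measuring it with calipers across a breeding trial is
slow and touches the plant. `stemdepth` implements a field-ready
alternative: a side-view RGB-D camera records a colour image and a
registered depth raster; the stem is segmented from the soil background,
reduced to a one-pixel centreline, and its diameter recovered as the 3-D
chord between the silhouette edges — no checkerboard or other reference
object required. The package also ships the matching evaluation suite, the
pinhole-imaging baseline it is compared against, and a synthetic
cylinder-scene renderer with exact ground truth so the whole pipeline is
testable offline.

## The method

For a scanline through a centreline point with edge pixels
$(x_1, y)$ and $(x_2, y)$ and shared surface depth $d$ (taken at the
centreline), each edge back-projects through the pinhole model

$$Z = d,\qquad X = \frac{x - c_x}{f_x}\,Z,\qquad Y = \frac{y - c_y}{f_y}\,Z,$$

is flipped from the image convention into the colour-stream point-cloud
frame ($y \to -y$, $z \to -z$), and mapped into the depth-stream frame by
the rigid extrinsic transform $p' = Rp + t$. The diameter is the Euclidean
distance $d = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}$ (identical in
every frame; rigid maps are isometries), and a stem's value is the median
of three scanlines. Processing stages: HSV hue gate + Otsu threshold on
saturation → median filter + morphological opening → largest 8-connected
component → internal-gradient contour and two-subiteration thinning →
scanline intersections → back-projection → diameter.

Agreement with manual measurements is scored with MAPE, MAE, RMSE, the
residual $R^2 = 1 - \sum_i (k_i - w_i)^2 / \sum_i (k_i - \bar k)^2$, Lin's
concordance correlation
$\rho_c = 2\rho\sigma_x\sigma_y / (\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2)$,
and a Wilcoxon signed-rank test.

## Worked example

Render a known scene (a 25 mm cylinder at 0.6 m, tilted 10° toward the
camera), then measure it:

```r
library(stemdepth)

sc <- render_scene(scene_spec(diameter_mm = 25, distance_m = 0.6, tilt_deg = 10))
sr <- measure_stem(sc$rgb, sc$depth, sc$spec$cam, roi = c(0.55, 0.80))
sr
#> <stem_result> diameter 24.24 mm (median of 3 scanlines, 0 failed)
tidy(sr)
#> # A tibble: 3 × 6
#>   center_col center_row left_col right_col depth_used diameter_mm
#>        <dbl>      <dbl>    <dbl>     <dbl>      <dbl>       <dbl>
#> 1        434        263     422.      446.      0.592        24.2
#> 2        434        323     422.      446.      0.602        24.7
#> 3        433        383     422.      446.      0.613        24.1
```

Each row is one scanline: the centreline point, the two contour
intersections, the depth fed to the back-projection (note it increases down
the tilted stem) and the resulting chord. The ~0.8 mm shortfall from the
true 25 mm is the documented centre-depth chord bias (~2% here) plus
sub-pixel discretisation; across the packaged 20-scene fixture suite the
mean absolute percentage error is ~2.1%.

The published 60-plant field comparison ships as data and reproduces its
printed statistics:

```r
rep <- stem_metrics(stem_tables()$table1)   # depth method vs caliper
rep
#> <metrics_report> n = 60
#>   MAPE 3.01%  MAE 0.75 mm  RMSE 1.07 mm
#>   R^2 0.96  CCC 0.978  Wilcoxon p 0.5029
#>   median measured 23.74 mm / true 23.63 mm
autoplot(rep)     # measured-vs-true scatter with the identity line
```

`measure_stem()` returns a `stem_result` with broom-style `tidy()` /
`glance()`; `run_pipeline()` drives a CSV manifest of frames and returns a
results tibble plus a batch `metrics_report`; `annotate_pointcloud()` marks
the measured 3-D coordinates in red in a PLY cloud for visual verification.
A thin command-line wrapper with `measure`, `batch`, `synth`, `metrics` and
`align` subcommands lives at `inst/cli/stemdepth.R`.

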