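# ecmarch

Quantification of extracellular-matrix (ECM) fiber architecture from
scanning electron micrographs, for researchers studying how the fibrous
scaffold of decellularized tissue — fiber diameters, pore sizes, and fiber
alignment — differs between experimental groups (for example tumor
xenografts from different cell lines). The same toolbox covers the
companion assays such studies lean on: cell-shape morphometrics, caliper
tumor volumes, oscillatory rheology crossovers, a fold-change/FDR
transcriptome screen, and cytokine-array normalization.

## What it computes

**Fiber segmentation.** A micrograph is split into fiber and pore phases
either by a trainable per-pixel classifier (a seeded random forest over a
multiscale feature stack: intensity, Gaussian-smoothed intensity, gradient
magnitude, and largest Hessian eigenvalue at scales {1, 2, 4} px) or by
deterministic thresholding (Otsu or fixed), after a percentile contrast
stretch.

**Fiber diameters.** The binary mask is axially thinned to 1-px
centerlines, and the exact Euclidean distance transform (EDT) D(x) gives
each fiber pixel's distance to the nearest pore. At a centerline pixel the
EDT is (approximately) the fiber radius, so the diameter there is

    d = 2 * D_ridge - 1   (px)

where D_ridge is the EDT read at the local ridge (8-neighborhood maximum)
and the −1 calibrates the pixel-count convention so a bar rendered t px
thick yields exactly t on axis-aligned fibers. Centerline pixels within
distance D(b) of a junction b (a skeleton pixel whose crossing number is
≥ 3) are excised before summarizing, since the EDT at fiber crossings
reflects the junction blob rather than either fiber.

**Pores and porosity.** Pores are 4-connected clusters of non-fiber pixels
fully surrounded by fiber: clusters touching the image border are excluded
(their extent is unknown) and clusters below a minimum detectable size
(default 10 px²) are treated as segmentation specks. Each retained pore is
measured (area, perimeter, ellipse-equivalent major/minor axes) and groups
are compared metric-by-metric with Welch's unequal-variance t-test,
Bonferroni-adjusted across metrics.

**Orientation and alignment.** The structure tensor — the Gaussian-windowed
(σ = 7 px) outer product of the image gradient — yields a per-pixel fiber
axis, coherence (λ₁−λ₂)/(λ₁+λ₂), and energy λ₁+λ₂. Angles are sampled on
the 2-px-dilated centerlines above a median-energy floor, histogrammed over
[−90°, 90°), and summarized by the nematic order parameter

    S = | mean( cos 2θ, sin 2θ ) |

which is 1 for parallel fibers and 0 for an isotropic network.

**Companion assays.** Cell circularity c = 4πA/P², aspect ratio from the
minimum-area rotated bounding rectangle, tumor volume V = 4/3·π·L·S²;
storage/loss-modulus crossover located by log–log interpolation of a
frequency sweep; gene screen retaining protein-coding transcripts and
calling genes up at fold change > 1.5 and down at < 0.5 with BH-adjusted
p < 0.05, then intersecting calls across cell lines; duplicate-spot
cytokine normalization (mean − background)/reference.

Every stage is validated against a synthetic-data module that renders
fibrous scenes (von Mises-distributed fiber axes on the doubled-angle
circle), cell outlines, Maxwell-model sweeps, planted expression tables,
and duplicate-spot arrays — all with exact ground truth.

## Worked example

```r
library(ecmarch)

# a 256x256 scene of 30 fibers, mean width 5 px, aligned around 30 degrees
spec  <- fiber_image_spec(n_fibers = 30, diameter_mean = 5,
                          orientation_mu = 30, orientation_kappa = 8,
                          seed = 42)
scene <- generate_fiber_image(spec)

mask  <- threshold_segment(adjust_contrast(scene$image), "otsu")
dd    <- estimate_fiber_diameters(mask, skeletonize(mask),
                                  distance_transform(mask))
pores <- detect_pores(mask)
field <- structure_tensor_field(scene$image)
ang   <- centerline_orientations(field, skeletonize(mask))

c(diameter = dd$summary$mean,
  n_pores  = nrow(pores),
  porosity = summarize_porosity(pores, mask)$pore_area_fraction,
  angle    = axial_mean(ang),
  S        = alignment_score(ang)$S)
```

```
 diameter   n_pores  porosity     angle         S
 5.294546 27.000000  0.158722 32.225171  0.971806
```

The estimated mean diameter recovers the planted 5 px width to about a
third of a pixel (fiber crossings merge into slightly thicker bundles in a
30-fiber scene), the recovered dominant angle is within ~2° of the planted
30° axis, and the order parameter S ≈ 0.97 reports a strongly aligned
network — the identical scene with `orientation_kappa = 0` scores S ≈ 0.31.

The same pipeline runs end to end with provenance:

```r
run_pipeline(pipeline_config(output_dir = "out", seed = 42,
                             simulate = list(n_fibers = 60)))
```

or from a shell via the bundled CLI
(`inst/cli/ecmarch run --out out seed=42`).

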