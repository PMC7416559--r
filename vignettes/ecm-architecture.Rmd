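---
title: "Quantifying fibrous ECM architecture: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrous ECM architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmarch)
```

This vignette is the package's own account of the methods it implements:
the measurement models, the parameters that matter and their defaults, the
numerical conventions, what the synthetic-data generator does and does not
emulate, and the design choices made where several reasonable options
existed.

## Conventions

Stated once and used everywhere: images are numeric matrices indexed
`[row, col]`, 1-based, origin at the top-left, intensities in [0, 1];
masks are logical matrices with `TRUE` = fiber. Angles are degrees on the
half-open axial range [−90°, 90°), with 0° along the +x (column) axis and
counter-clockwise positive when the y axis points up (i.e. rows
decreasing). Orientations are *axial* — a fiber at 95° is the fiber at
−85° — so all circular statistics run on doubled angles. Physical
calibration is a `pixel_size` attribute in nm/px and is purely
multiplicative; it must be supplied by the user, since magnification alone
does not determine it.

## Segmentation

Micrographs are first contrast-stretched between the 1st and 99th
intensity percentiles (robust to a few saturated pixels; a constant image
is returned unchanged with a warning, since there is nothing to stretch).

Two segmentation routes produce the binary fiber mask:

* **Trainable classification.** A per-pixel feature stack — raw intensity
  plus, at each scale σ ∈ {1, 2, 4} px, the Gaussian-smoothed intensity,
  gradient magnitude, and the largest Hessian eigenvalue (a ridge
  detector, apt for curvilinear fibers) — feeds a random forest of 100
  trees trained on sparse user annotations. Both training and prediction
  are pure functions of their inputs and a seed: the forest's own seed is
  fixed, the R RNG is pinned during fitting, and prediction tie-breaking
  is seeded, so a stored classifier always reproduces its masks.
* **Thresholding.** Otsu's criterion (or a fixed threshold) for pipelines
  without annotations. The default polarity expects fibers brighter than
  background, the usual secondary-electron contrast of sputter-coated
  fibrous samples; a flag inverts it.

One numerical subtlety: Gaussian smoothing uses an FFT-based convolution,
which returns a constant image only to ~10⁻¹⁷. Derivative features are
therefore computed by central differences *before* smoothing (the two
linear operators commute), so a flat image has exactly zero gradient,
Hessian, and tensor energy — degenerate inputs degrade cleanly rather
than into numerical dust.

## Fiber diameters from centerline EDT

The mask is axially thinned (Zhang–Suen) to 1-px centerlines after
dropping fiber components under 10 px (specks carry no diameter
information). The exact Euclidean distance transform D assigns each fiber
pixel its distance to the nearest non-fiber pixel; along a centerline D is
the local fiber radius, and the per-pixel diameter is `2·D_ridge − 1`.

Two calibration details deserve explanation:

* **The −1.** For a horizontal bar rendered t px thick (t odd), the center
  row sits (t+1)/2 px from the nearest *background pixel center* — pixel
  counting, not geometry, adds half a pixel on each side. Plain doubling
  would report t+1 for every axis-aligned bar; the −1 makes the estimate
  exactly t there.
* **The ridge reading.** Thinning places an oblique centerline on a
  staircase that wanders up to half a pixel off the true EDT ridge, which
  biases oblique diameters low by up to ~1.5 px. Reading D as the maximum
  over the centerline pixel's 8-neighborhood (restricted to fiber pixels)
  recovers the ridge value. With it, planted widths of 3, 5, and 9 px are
  recovered within ±1 px at probe angles of 0°, 20°, and 70°, noiseless
  and at noise sd 0.05 (worst case under 0.8 px across seed sweeps, and
  exact on axis-aligned bars). The one geometry outside the window is the
  smallest width on an exact 45° diagonal, where the square lattice makes
  the rendered width itself ambiguous — a limitation of pixel geometry,
  not of the estimator.
* **Border censoring.** A centerline pixel whose distance value exceeds
  its distance to the image frame sits on a fiber cut by the frame: its
  true radius is unknowable (the transform only saw the interior side),
  so such pixels are excluded — the same reasoning that excludes
  border-touching pores. Without this rule, fibers clipped at the frame
  edge report up to 2 px of spurious extra width.

**Junctions.** Where fibers cross, the EDT reflects the merged junction
blob rather than either fiber, so centerline pixels within distance D(b)
of each branch point b are excised before summarizing (ties at exactly
D(b) are removed). Branch points are defined by the 8-neighborhood
*crossing number* — the count of 0→1 transitions around the pixel — being
at least 3. A raw neighbor count of ≥ 3 looks equivalent but is wrong in
practice: every step of a diagonal centerline's staircase has three
neighbors, so a neighbor-count rule flags nearly all oblique fiber pixels
as junctions and the correction would delete most of the centerline. The
crossing number is 2 everywhere along a line, whatever its angle, and ≥ 3
only at true meetings of three or more line segments. On axis-aligned
crossings the correction strictly reduces the diameter bias; on oblique
crossings the ridge-read estimator is already nearly unbiased and the
correction moves the mean by under 0.1 px.

## Pore census

Pores are connected clusters of non-fiber pixels fully surrounded by
fiber. Background clusters use 4-connectivity against 8-connected fiber —
the standard digital-topology pairing that prevents fiber and pore phases
from crossing through the same diagonal. Clusters touching any image
border are excluded because their true extent is unknown; clusters under
`min_size` (default 10 px², user-overridable — the threshold exists to
absorb single-pixel segmentation errors, and no principled value follows
from the imaging physics) are excluded as specks. Excluded components are
retained in an attribute so pixel accounting stays exact.

Per-pore geometry: area (pixel count); perimeter as the count of exposed
pixel faces minus (2 − √2) per right-angle boundary corner, a documented
convention that brings staircase contours close to the length of the
underlying smooth outline (absolute perimeters are always
convention-dependent at pixel scale); major and minor axis lengths from
the ellipse with the same second central moments, with a 1/12 per-pixel
variance term so even a single pixel has positive extent.

Group comparisons use Welch's unequal-variance t-test with
Welch–Satterthwaite degrees of freedom — different scaffolds yield
different pore counts, so equal-variance pooling is inappropriate — and
Bonferroni adjustment across the (at most four) pore metrics compared.

## Orientation and alignment

The structure tensor is the Gaussian-windowed outer product of the image
gradient. Gradients are central differences after 1-px pre-smoothing; the
window is a Gaussian of σ = 7 px by default. A "7-px window" could also be
read as a full width of 7 px (σ ≈ 3); σ is a single explicit parameter,
and the larger default was chosen because tensor averaging must span at
least a fiber width to give stable axes at the 5–10 px fiber scales the
package targets.

For an intensity image, the tensor's *dominant* eigenvector points across
the texture (maximal intensity variation); the fiber axis is the
perpendicular, minimal-variation direction, and that is what the package
reports. Coherence (λ₁−λ₂)/(λ₁+λ₂) discriminates oriented texture (→ 1)
from isotropic structure (→ 0); energy λ₁+λ₂ separates textured pixels
from flat background, and pixels with zero energy have an undefined (NA)
angle.

Angles are sampled where fibers actually are: on the centerlines dilated
by 2 px (a disc radius; the dilation smooths staircase jitter in the
sample), keeping pixels above a median-energy floor so background pixels
swept in by the dilation do not dilute the sample. The angular histogram
(36 bins of 5° by default) uses circular peak detection; the scalar
summary is the nematic order parameter S, the resultant length of the
doubled-angle unit vectors: 1 for parallel fibers, 0 for isotropic. On
analytic sinusoidal gratings the recovered axis is within 1.4° of truth at
0°, 30°, 60°, and −45°, and rotation of the scene shifts the recovery
equivariantly. No fixed S cutoff is asserted for calling a network
"aligned" versus "random": S is continuous and the package reports it as
such.

## Morphometry and companion assays

Circularity c = 4πA/P² (π at machine precision; the printed two-decimal
approximation sometimes used in reports differs by < 0.06%), aspect ratio
as length:width of the *minimum-area rotated bounding rectangle* — a
reproducible operationalization of hand-measured cell length and width,
computed by rotating calipers on the convex hull. Polygon area is the
shoelace formula and perimeter the closed vertex-chain length;
self-intersecting outlines are rejected. Tumor volume is the two-radius
ellipsoid formula V = 4/3·π·L·S², with inputs auto-reordered (and a
warning) if the smaller radius is passed first. Two-group comparisons use
the unpaired t-test (equal-variance by default, Welch optional); three or
more groups use one-way ANOVA with Tukey's HSD.

The rheology stage locates the storage/loss-modulus crossover — the
frequency where G″ overtakes G′, a proxy for network cross-linking — by
finding sign changes of log G′ − log G″ along the sweep and interpolating
linearly in log–log space. Moduli span decades, so linear-space
interpolation would bias the crossover; on noiseless single-mode Maxwell
data the log–log rule is exact (the crossover sits at ω = 1/τ, and log
G′ − log G″ = log ωτ is linear in log ω). Exact ties at a grid point
report that grid frequency; multiple crossovers are all reported with the
first flagged primary.

The expression screen removes five non-coding biotypes (lincRNA, miRNA,
3′-overlapping ncRNA, processed pseudogene, antisense), keeps unknown
biotypes with a warning (a conservative default: silent deletion of
unrecognized annotation classes is worse than a warning), adjusts raw
p-values by Benjamini–Hochberg (the method is a documented, swappable
choice wherever only "FDR correction" is specified), and calls genes up at
fold change strictly above 1.5 and down strictly below 0.5, both at
adjusted p < 0.05 — boundary values are deliberately excluded, reading
"above" and "below" literally. The five classes (up, down, unchanged,
not-significant, excluded-biotype) partition every table exactly. Cytokine
spots are normalized as (mean of duplicates − background)/reference,
floored at zero: background exceeding signal is noise, not negative
abundance.

## The synthetic-data generator

Every stage is validated against scenes with exact ground truth:

* **Fibrous images.** Straight, constant-width bars with axes drawn from a
  von Mises distribution on doubled angles (κ = 0 isotropic; large κ
  aligned about the mean axis), rendered by the rule *pixel center within
  half a width of the fiber axis* — which makes a width-w bar exactly w px
  thick for almost every sub-pixel offset — then Gaussian-blurred, noised,
  and clipped. The mask and per-fiber records are recorded before
  degradation, and `true_porosity` is the exact non-fiber pixel fraction.
* **Cell outlines.** 720-vertex ellipse discretizations at constant area
  across elongations; elongation dispersion defaults to zero so the
  recorded axis ratio equals the requested elongation exactly.
* **Rheology.** Single-mode Maxwell sweeps G′ = Gω²τ²/(1+ω²τ²),
  G″ = Gωτ/(1+ω²τ²) on a default grid spanning 0.628–62.8 rad/s, with
  optional multiplicative lognormal noise (so 2% noise is `noise_sd =
  0.02` and moduli stay positive).
* **Expression tables.** Planted up/down protein-coding genes at a
  guaranteed effect fold with small p-values, null genes lognormal about
  fold 1 with uniform p, across six biotypes in realistic proportions
  (70% protein-coding).
* **Cytokine arrays.** Duplicate spots around background + level·reference
  with per-spot noise and the exact normalized level recorded.

All generators are pure functions of (spec, seed).

**What the generator does not emulate** — and therefore what passing tests
do not show about real micrographs: fibers are straight, unbranched, and
of constant width (real ECM fibers curve, branch, and taper); the noise
model is Gaussian blur plus additive Gaussian noise (no charging
artifacts, shading gradients, or depth-of-field effects of real SEM); the
scene is 2-D (a real micrograph is a projection of a 3-D network, so
measured "pores" are projected inter-fiber gaps, not volumetric pores).
Validation on these scenes establishes that the estimators are correct and
calibrated under their stated model; accuracy on real tissue additionally
depends on segmentation quality and on how far the specimen departs from
that model.

## Validation problem sizes

The shipped tests and the acceptance script run, per invocation: 128–192
px synthetic scenes (single fibers for diameter probes, anchored at least
32 px from the frame so the calibration geometry is well posed, and
thresholded at the known intensity midpoint because a one-fiber histogram
is essentially unimodal and offers Otsu no valley; 25–40 fibers for
alignment and pipeline runs); 50 random masks up to 40×40 for the exact
EDT-versus-brute-force check; 12 random 30×30 masks plus hand fixtures
for the pore-census oracle; 2,000-gene screens; all 120 permutations of
five p-values against a step-up oracle; 20 images per cohort for the
pore-shift power check; and two full pipeline runs compared byte for
byte. These sizes were chosen so the complete validation runs in well
under a minute while every check retains a comfortable margin over its
threshold.

## Known limitations

* Diameters at fiber crossings are excised, not apportioned; per-fiber
  instance statistics (length, tortuosity) are out of scope.
* The pore perimeter and axis conventions are pixel-scale conventions;
  compare like with like when mixing tools.
* The trainable classifier matches the *family* of the interactive
  tools common in this field (a seeded tree ensemble over multiscale
  features), not any specific tool's exact feature menu, so masks are not
  expected to be byte-identical to theirs.
* Physical units depend entirely on the user-supplied nm/px calibration.
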