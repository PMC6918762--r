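---
title: "Quantifying nest camouflage and egg heating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nest camouflage and egg heating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nestcamo` quantifies two things about the nests of ground-nesting birds
such as the Kentish plover: how well the eggs and the nest materials blend
into their surroundings (camouflage), and how fast model eggs heat up on
different nest materials (thermal behaviour). This vignette explains the
models and procedures, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## Camouflage by texture analysis

### The pipeline

A nest photograph is analysed as a calibrated, linear-RGB raster with a
region-of-interest mask separating four areas: the eggs, the nest cup, a
thin internal buffer ring around the nest, and the surrounding microhabitat
(the "external" region). The analysis proceeds in five steps.

1. **Margin exclusion.** A thin frame around the picture border
   (`margin_fraction`, default 0.02 of the shorter image side) is excluded:
   outer pixels of real photographs are the least trustworthy (vignetting,
   demosaicing artefacts). The operation is idempotent and conserves pixel
   counts.

2. **Calibration and colour.** Linear pixel values are divided by the
   measured value of an in-scene gray standard (18% nominal reflectance by
   default) so the image is expressed in reflectance units, and then
   converted to CIE L\*a\*b\*. The adapted white point is the scene's
   neutral axis: a pixel with equal R, G and B maps exactly to
   a\* = b\* = 0, and the gray standard itself maps to L\* ≈ 49.5. The
   conversion is invariant to global exposure scaling by construction.
   Values that clip after normalisation are counted; more than 1% of
   clipped pixels triggers an overexposure warning (overexposed close-up
   photographs are unusable and were discarded in the field protocol this
   reimplements).

3. **Texture features.** Each of the L\*, a\*, b\* channels is filtered
   with a multi-scale bank. Per scale σ the bank holds `n_orientations`
   odd-symmetric and `n_orientations` even-symmetric oriented kernels
   (orientations evenly spaced over [0°, 180°)) plus four
   rotation-invariant members: Gaussians at σ/2 and σ and
   Laplacian-of-Gaussian kernels at σ/2 and σ. With the field-protocol
   defaults — four scales σ = {16, 24, 32, 48} px and five orientations —
   this is 14 kernels per scale, 56 per channel, 168 features per pixel.

4. **Clustering.** The feature vectors of every analysed pixel of *one*
   image are clustered with K-means (`n_clusters` = 14 by default).
   Signatures are only ever compared within an image, so cluster
   identities need not align across images. Each region's *clustering
   signature* is the percentage of its pixels in each cluster — a
   normalised texture histogram.

5. **Scores.** Background/pattern matching between two regions is the
   chi-squared histogram distance between their signatures,
   ½ Σᵢ (gᵢ − hᵢ)² / (gᵢ + hᵢ), zero bins skipped. It ranges from 0
   (identical texture composition) to 100 (disjoint support); *lower is
   better camouflage*. It is symmetric and zero iff the signatures are
   equal, but it is not a metric — the triangle inequality can fail, so it
   is a dissimilarity score, not a distance in the mathematical sense.

### Kernel construction

The classic oriented texture-analysis set is used: the even-symmetric
member is the second derivative of an elongated Gaussian (3:1 aspect,
derivative across the short axis) and the odd-symmetric member is its
Hilbert-transform pair along the same axis, computed by a discrete FFT
Hilbert transform of the 1-D cross-section and interpolation onto the
rotated grid. Kernels are sampled on a `2*ceiling(2*sigma)+1` window (±2σ,
bounding cost while keeping the response mass) and L1-normalised —
zero-mean families by their absolute sum, plain Gaussians to unit sum — so
response magnitudes are comparable across scales before clustering.
Filtering uses the image-processing convention (sliding inner product): an
impulse responds with the flipped kernel. The production path is FFT-based
with reflect padding and is tested to 1e-8 against a direct-summation
reference on small inputs.

Per-feature standardisation before K-means is available
(`standardize = TRUE`) but off by default: the protocol this package
follows specifies none, and the L1 normalisation already balances scales.

### K-means details

K-means uses k-means++ seeding with 10 restarts and Lloyd iterations
(via `stats::kmeans`), all under a caller-supplied seed, because
reproducibility of the texture map is part of the contract: the same scene
and seed must give byte-identical labels, boundaries and scores. If an
image has fewer distinct feature vectors than requested clusters (a flat,
synthetic edge case), the cluster count is reduced with a warning; a fully
constant image yields a single cluster and an empty boundary image.

### Choosing the number of clusters

`select_n_clusters()` reruns the pipeline over a set of scenes for each
candidate count (default {6, 8, 10, 12, 14, 16, 20}) and averages, per
candidate, the correlation between the egg and external signatures. As the
cluster count grows this correlation decreases and saturates; the chosen
count is the smallest candidate after which the decrease falls below `tol`
(default 0.02). Pearson correlation is the default; whether the original
analysis used Pearson or a rank correlation is not documented, so a
`method` flag exposes both.

### Disruptive camouflage

The disruptive score asks how much of the egg *outline* the texture
analysis can see. The one-pixel inner border of each egg instance is
dilated with a cross-shaped structuring element whose radius is 1% of the
mean egg length (major axis of the best-fit ellipse, in pixels; floor of
1 px), intersected with the texture-frontier image, and the intersection is
thinned back to unit width (Zhang–Suen). A border pixel counts as detected
when a thinned frontier pixel lies within the dilation radius; the score is
the detected percentage of border pixels, pooled over eggs (per-egg values
are also reported). Lower scores mean a better-disrupted outline. Texture
frontiers are defined by 4-connectivity label changes, marked one pixel
thick on the lower-label side, which makes the frontier image reproducible;
the intersection tolerates 8-connected matches through the distance-based
attribution.

### Coverage of experimental material

`coverage_percent()` reproduces the close-up protocol: a grid of
`square_mm` × `square_mm` squares (default 2 mm, converted through the
pixel scale) is anchored at the corner of the nest-region bounding box.
Squares at least half inside the nest are counted, and a square is
"dominated" when material pixels exceed half of its in-nest area. How the
original tool treated partial edge squares is undocumented; the ≥50%-inside
rule was chosen because it is deterministic, testable, and unbiased at the
region boundary. The percentage is exactly invariant to translating both
masks by whole squares and monotone in the material mask under inclusion.

## Newtonian heating

Under constant irradiation, an egg whose internal heat redistribution is
fast relative to its surface exchange follows Newtonian heating: the
shifted temperature y(t) = T(t) − T_f decays as y = a·e^{bt} with
a = T_i − T_f and b = −1/Tc. Tc, the *characteristic heating time*, is the
time at which 100·(1 − e⁻¹) ≈ 63.2% of the total temperature change is
complete — the single-number summary of how fast eggs heat on a given
material.

`fit_heating()` fixes T_f from the data, shifts the series and fits (a, b)
by Levenberg–Marquardt nonlinear least squares with deterministic start
values (a₀ from the first shifted record; b₀ from a log-linear regression
over the first half of the series). Two design points deserve note:

* **T_f anchoring.** T_f is the mean of the last `tail_k` records
  (default 5) rather than the bare final record. With a single noisy
  record anchoring the shift, the anchor's measurement error propagates
  into Tc and dominates its estimation error; averaging a short tail
  removes most of that variance while leaving noiseless series essentially
  exact (the residual terminal transient is e^{−D/Tc} of the amplitude for
  a run of duration D). `tail_k = 1` restores the single-record rule.
* **Two parameters, not three.** T_f is data-anchored, not fitted: the
  model form is y = a·e^{bx} on the shifted series. A three-parameter fit
  would absorb anchor error but changes the model actually specified for
  this analysis.

The fit reports r² on the shifted series. Fits are deterministic given the
data. Degenerate inputs — fewer than 10 samples, a temperature range under
0.5 °C, non-increasing time stamps — are rejected with specific errors, and
a fitted b ≥ 0 (a series running away from its final value) is refused as
"not a heating curve".

For field series, where convection makes some materials (twigs) deviate
from the exponential, no Tc is estimated; the summary is the mean of the
last five records of the series cropped to the 1111 s protocol window
(`crop_series()` + `summarize_final_temperature()`). The
reflectance–temperature relationship across materials uses a Spearman rank
correlation with the exact permutation p-value for n ≤ 8 (ties get average
ranks, in which case the p-value is approximate).

## The synthetic-data generator

No photographs or thermocouple logs are distributed with this package, so
`make_scene()` and `make_heating_curve()` generate seeded inputs with the
statistical structure the analyses assume.

A synthetic scene is a neutral (a\* = b\* = 0) linear-RGB raster in
reflectance units: nested regions (elliptical eggs inside a nest disc,
separated from the microhabitat by an internal ring of at least 1 px), each
textured by thresholding low-pass-filtered seeded Gaussian noise into
two-level pebble-like patches at the region's mean lightness ± half its
contrast. The default region lightnesses are the field means observed in
unmanipulated nests — egg L\* 25.31, nest 32.28, microhabitat 28.42 — so
that default scenes reproduce the observed ordering (nests lighter than
microhabitats, eggs darkest). Grain sizes (1.5–3 px) and contrasts (6–8 L\*
units) were chosen once as visually plausible pebble textures at the
generator's 128-px scene scale and are exposed in `scene_spec()`.
Treatments mirror the field experiment: `"T"` retextures the nest with a
material of lightness `material_L`; `"W"` retains material patches over
`retained_fraction` of the nest area (default 0.15, the field estimate of
material left one week after manipulation). A gray-standard patch of known
value is rendered in a corner and excluded from analysis. All generation
parameters are stored as ground truth beside the outputs.

Heating curves are exact exponentials plus Gaussian noise (default sd
0.2 °C) on the laboratory sampling protocol (15 s interval, 60 min,
i.e. 241 records).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: natural pebble shapes and shadows, chromatic
variation (synthetic scenes are neutral, so the a\*/b\* channels carry no
signal), illumination gradients, camera noise and optics, egg maculation,
and the convection that makes real twig series non-exponential. Tests on
synthetic scenes validate the machinery and its statistical behaviour, not
field-level effect sizes.

### Problem sizes

Synthetic scenes are rendered at 96–256 px — roughly a tenfold linear
reduction from the multi-megapixel field frames — so analyses of synthetic
scenes use bank scales reduced in proportion (2–8 px instead of 16–48 px)
and modest cluster counts (2–6). These sizes were chosen so the whole
analysis suite, including parameter-recovery simulations with 100 heating
curves, runs in minutes on a laptop; the structural constants of the
field-protocol bank (56 members, 168 features) are still verified at full
scale.

## Numerical choices and edge cases

* Chi-squared distance uses the ½ factor of the histogram-comparison
  literature; `half = FALSE` gives the no-½ variant. Inputs must sum
  to 100 (tolerance 1e-6); zero-sum bins are skipped.
* Polygon masks are rasterised with the even-odd rule at pixel centers,
  0-based row/col coordinates.
* Egg length on a raster is defined as the major-axis length of the
  best-fit ellipse (4·sd of pixel coordinates along the principal axis),
  which equals the true major axis for an ideal filled ellipse.
* The Lab reference white is taken from the colour-conversion library's
  own Lab(100, 0, 0) → XYZ round trip rather than hard-coded constants, so
  neutral pixels map to a\* = b\* = 0 exactly regardless of the library's
  internal white-point convention.
* K-means++ seeding cannot duplicate a center (a chosen point has zero
  distance mass), so no jitter is needed.
* The cross-shaped structuring element radius is `round(0.01 · mean egg
  length)` with a floor of 1 px; on strongly downsampled synthetic scenes
  this floor makes the disruptive score sensitive to frontier placement
  within a pixel or two, which is why synthetic disruptive checks use
  fine bank scales.

## Known limitations

* Camouflage scores are texture-statistical, not perceptual: no predator
  visual system, spectral sensitivity or viewing distance is modelled.
* Clustering is per image; scores are comparable within an image and, as
  distributions, across images, but cluster identities are not.
* The chi-squared score is bounded by the signature representation; two
  regions with identical texture histograms but different spatial layouts
  score 0.
* RAW decoding is out of scope; inputs must be linearised rasters
  (16-bit TIFF/PNG). An ingestion hook can wrap an external RAW decoder.
* Inferential statistics on the scores (mixed models, post-hoc tests) are
  left to standard tools downstream of the CSV outputs.

## Reproducing an analysis

```{r example}
library(nestcamo)

sc <- make_scene(scene_spec(size = c(128, 128), treatment = "T",
                            material_L = 60, seed = 1))
std <- gray_standard(0.18)
cfg <- run_config(scales = c(2, 4), n_orientations = 3, n_clusters = 6,
                  seed = 1)
run_scene_pipeline(list(nest1_T = sc), std, cfg)
```

The `analysis/` directory of the source repository contains the numbered
drivers that generate the full synthetic study set (`01_simulate.R`),
score camouflage across O/T/W treatments (`02_camouflage.R`), measure
retained-material coverage (`03_coverage.R`) and fit the heating curves
(`04_heating.R`), each writing its tables under `results/`.
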