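---
title: "Splitting touching soybean seeds from scene images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting touching soybean seeds from scene images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedseg)
```

## The problem

Seed-quality image datasets are built by photographing many seeds at
once on a dark tray and cutting each seed out as its own small image.
Two things make this harder than it sounds. First, raw photographs have
uneven illumination and muted contrast, which destabilizes global
thresholding. Second, seeds poured onto a tray frequently touch: after
binarization, two touching seeds form one connected blob, and a naive
component analysis emits one merged crop where there should be two.
`seedseg` addresses both: retinex-based enhancement normalizes
illumination before thresholding, and clusters of touching seeds are
detected from their bounding-rectangle size and split apart before
cropping.

The pipeline assumes the imaging regime of a seed light box: convex,
roughly ellipsoidal objects, all of similar size, brighter than a dark
background, in *tiny* contact — thin bridges of touching pixels rather
than deep overlaps. Seeds occluding each other or piled in heaps are
out of scope.

## Pipeline stages and their parameters

### MSRCR enhancement

Multi-scale retinex with color restoration computes, per channel $i$
and surround scale $\sigma$,

$$R_{\sigma,i} = \log(I_i + 1) - \log(G_\sigma * I_i + 1),$$

where $G_\sigma$ is a normalized Gaussian. The multi-scale response is
the weighted sum over scales, multiplied by the color-restoration
factor

$$C_i = \beta\,\big[\log(\alpha I_i + 1) - \log(I_R + I_G + I_B + 1)\big],$$

and mapped linearly to 0–255 with clipping at configurable percentiles.
Defaults are the canonical values from the retinex literature:
scales $\{15, 80, 250\}$ px with equal weights (fine detail, regional
context, near-global illumination), $\alpha = 125$, $\beta = 46$, and a
1%/99% percentile stretch. All are overridable through
`retinex_params()`. Percentile stretching is per-channel by default; a
luminance-based variant (one clip range shared by all channels, which
preserves chromaticity ratios exactly) is available via
`stretch_mode = "luminance"` for users who find per-channel stretching
shifts hue too aggressively.

The $+1$ inside every logarithm keeps zero-valued pixels finite; natural
logs are used throughout. Gaussian kernels are sampled at integer
offsets, normalized, truncated at $3\sigma$, and applied with
mirror-reflection boundary handling so dark halos do not form at the
image border. Two evaluation routes compute the identical convolution:
direct separable convolution for kernels up to 129 taps, and an
FFT route for wider surrounds, which exploits the fact that circular
convolution of the symmetric two-fold extension of an image equals
reflection-boundary convolution exactly. The two routes agree to about
$10^{-13}$ on 8-bit data, far below the quantization step; the test
suite asserts their agreement explicitly.

### Binarization

The enhanced scene is converted to grayscale with ITU-R 601 luma
weights and thresholded at the Otsu optimum — the level $t$ maximizing
the between-class variance $\omega_0\omega_1(\mu_0-\mu_1)^2$ over all
256 candidates. Ties break toward the lowest level, making the result
deterministic. A single-valued image has no variance to split and
raises a degenerate-histogram error, which the pipeline converts into
an empty result with a warning record rather than a crash (a blank tray
photograph is an operational reality, not a programming error).

### Localization and contact judgment

Foreground components (8-connected) become tight axis-aligned minimum
bounding rectangles. "Minimum bounding rectangle" is read as the
axis-aligned tight box, not the rotated minimum-area rectangle: the
final outputs are axis-aligned square crops, so a rotated rectangle
would only add a conversion step with no effect on the result.
Components below a minimum area — by default 10% of the scene's median
component area, with an absolute floor of 32 px² — are discarded as
debris.

A rectangle is judged to hold *touching* seeds when it is markedly
larger than a single-seed reference: area above `area_ratio` (default
1.5) times the reference area, or longest side above `side_ratio`
(default 1.4) times the reference side. The reference is the median
box area of the scene, which is robust because touching clusters are a
minority of components in this imaging regime. Both ratios and an
explicit calibrated reference are configurable via `contact_rule()`.
The two-part rule covers both geometries of a merged pair: an
axis-aligned pair roughly doubles one side (caught by the side test),
while a diagonal pair inflates the box area quadratically (caught by
the area test). The rule errs toward sensitivity on purpose — a single
seed sent through separation comes back as one box essentially
unchanged, whereas a missed pair always produces one improper output.

### Separation

Flagged clusters are masked out of the binary image individually (the
cluster's component pixels inside its rectangle) and split by one of
two methods:

- **EOP** — morphological erosion with a square structuring element
  (default 13×13). Erosion removes any contact bridge thinner than the
  kernel while convex seed cores survive; the eroded components are
  re-located by tight rectangles. Because erosion shrinks every
  component by the kernel radius per side, the boxes are compensated —
  expanded back by $(k-1)/2$ px per side, clamped to the scene — before
  cropping. Linear radius compensation is exact for rectangles and
  slightly conservative for ellipses (erosion by a square removes a bit
  more than the radius near high-curvature ends), which biases crops
  toward including the whole seed: the right direction for a dataset
  tool. If erosion eliminates a cluster entirely, the original cluster
  box is returned flagged `unseparated` — a seed region is never
  silently dropped.
- **WA** — marker-based watershed. Markers are local maxima of the
  Euclidean distance transform of the cluster, thinned to a minimum
  mutual separation (default: half the scene's median seed side, the
  standard recipe for touching convex objects); basins are grown from
  the markers over the cluster foreground by seeded region growing on
  the distance map. The basins partition the cluster exactly — the
  test suite asserts disjointness and union-exactness pixelwise.

Erosion is applied per cluster rather than globally so that untouched
seeds keep their exact outlines, and the erosion-then-relocate step
only runs where the contact judgment says it must.

### Extraction

Each final box, expanded by a small margin (default 2 px), is cropped
from the *enhanced* scene (a flag switches to raw-scene crops), centered
on a square canvas filled with the scene's median background color —
avoiding the artificial hard edges black padding would create — and
resized to 227×227 with bilinear interpolation. Bilinear was chosen
because no installed imaging package exposes area-average resampling
and the scale change for near-square seed crops is mild; for the
shrink factors involved (roughly 0.5–2×) the two interpolators differ
by at most a few gray levels per pixel. A region that is already a
227×227 square passes through pixel-identical.

## Accuracy metric

Segmentation accuracy is the number of properly segmented
individual-seed outputs divided by the total number of segmented
outputs. The denominator is the *outputs*, not the ground-truth seeds;
a missed seed therefore does not lower the accuracy, and
`match_boxes()` reports recall separately as a diagnostic.
"Properly segmented" is operationalized as greedy one-to-one matching
by descending IoU with a 0.5 threshold — the standard detection
criterion: it is monotone in overlap, automatable, and fails both
merged clusters (one box spanning two seeds has IoU < 0.5 with each)
and fragments. The threshold is configurable. Greedy matching can in
principle fall below the optimal assignment on pathological overlap
patterns; the test suite checks it against an exhaustive-assignment
oracle on small random instances.

## The synthetic benchmark

`generate_scene()` renders what the camera rig produces: bright convex
seed blobs on a dark background with a controllable fraction of
touching pairs. Specifically — rotated ellipses with major semi-axis
20–26 px and aspect ratio 0.75–1 at the default 1024×683 scene scale
(soybeans are near-spherical and commercially size-graded, so low size
dispersion is the realistic regime), ochre base color with per-seed
jitter, a 15% horizontal illumination ramp, additive Gaussian noise
(σ = 4 gray levels), and 8-bit quantization. Placement is by dart
throwing with a guaranteed ≥ 6 px boundary gap between non-designated
seeds; designated pairs are placed 2 px apart along the line of centers
and joined by an explicitly drawn bridge of configurable width (default
3 px). Drawing bridges explicitly, rather than letting ellipses
overlap, pins down the exact contact width — the quantity the erosion
kernel acts against — so the benchmark probes the regime the method is
designed for. Everything is a pure function of the configuration's
RNG seed; scenes and ground truth regenerate bit-identically.

What the generator does *not* emulate: specular highlights, soft
shadows around seeds, chromatic aberration, seed-surface texture
(hilum, wrinkles, disease spots), partial occlusion, and deep overlap
of touching seeds. Passing the benchmark therefore demonstrates that
the geometry of the pipeline — thresholding, localization, contact
judgment, bridge-breaking, compensation, matching — is correct under
controlled contrast and contact width; it does not certify accuracy on
any particular real camera rig, where contact widths and contrast are
not controlled.

The standard benchmark used by the test suite and the acceptance
script is 50 scenes of 40 seeds (2,000 seeds, 20% in touching pairs,
3-px bridges) at 1024×683 — a deliberate desk-scale choice that keeps
a full method/kernel sweep in the minutes range while giving
percentage-level resolution (one improper output changes accuracy by
0.05%). On this benchmark, 13×13 erosion separates every pair; the
3×3 kernel, narrower than the bridges, leaves some pairs merged, which
is exactly the monotone kernel-size trend the sweep is designed to
expose. Scene size, seed count and bridge width are all configurable
for users who want the full 3072×2048 regime.

## Numerical and degenerate-case choices

- Box coordinates are 0-based with x = column, y = row, half-open
  $[x, x+w) \times [y, y+h)$; boxes are emitted in row-major order of
  their top-left corner, so outputs are byte-reproducible.
- Erosion semantics: pixels outside the image count as background, so
  objects touching the border erode there too; this keeps the
  composition law `erode(k1) ∘ erode(k2) = erode(k1 + k2 − 1)` exact.
- Otsu ties break toward the lowest level; the percentile stretch with
  a flat (zero-variance) retinex response maps to mid-gray 128.
- A constant scene enhances to a constant scene; an all-background
  scene yields zero crops plus a warning record.
- Erosion of a whole cluster to nothing, or a watershed finding no
  markers, returns the original cluster box flagged `unseparated`.
- All tolerances asserted in tests are either exact (integer or
  byte-level identity for deterministic paths) or explicit FP bounds
  (about $10^{-9}$ for the two convolution routes).

## Known limitations

- Deeply overlapping seeds (contact wider than any reasonable kernel)
  defeat erosion; watershed handles moderate necks but not heaps.
- The contact judgment assumes one dominant seed size per scene; a
  scene mixing two very different seed calibers would need an explicit
  calibrated reference instead of the median rule.
- Axis-aligned rectangles overcover elongated seeds lying diagonally;
  crops still contain the whole seed but include more background.
- Accuracy as defined ignores missed seeds; use the reported recall
  alongside it when tuning the minimum-area filter.
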