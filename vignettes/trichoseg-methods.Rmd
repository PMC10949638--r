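---
title: "Quantifying leaf hairiness from microscopy images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf hairiness from microscopy images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The phenotyping problem

Leaf hairiness (pubescence) is the density of trichomes — thin, bright,
hair-like epidermal cells — on the underside of a leaf. In cotton it
affects insect resistance, fibre yield and fibre value, and breeders have
traditionally scored it by eye on an ordinal Genotype Hairiness Score
(GHS) scale from "1" (glabrous) to "5+" (pilose). That scale is
qualitative, non-linear, and attributed per genotype rather than per
image. `trichoseg` implements the quantitative alternative: segment every
trichome pixel in a leaf-surface microscopy image and summarise the image
by the **Leaf Trichome Score**

$$\mathrm{LTS} = \frac{N_S \times 1000}{N_T},$$

where $N_S$ is the number of pixels segmented as trichome and $N_T$ the
total number of pixels. The factor 1000 rescales the very sparse
foreground fraction to an interpretable 0–1000 range. LTS is exactly
invariant under integer nearest-neighbour upscaling of a mask (both
counts scale together), so the choice of working resolution is benign for
a fixed pipeline; we compute it at the prediction's working resolution.

Segmentation is the classic binary-mask estimation problem: find the mask
$M^\ast = \arg\min_M E(M)$ with $m_{xy}\in\{0,1\}$, optimised here through
differentiable surrogate losses (below) on a per-pixel probability map.

## Spline annotations, not masks

Trichomes are one or two pixels wide and hundreds of pixels long.
Annotating them as dense masks at a fixed resolution would be both
wasteful and brittle: resizing a thin-structure mask with any
interpolation scheme breaks long annotations into fragments or merges
neighbours. Annotations are therefore stored as ordered spline control
points at a reference resolution and rendered to masks on demand:

* **Interpolation family.** The control points are interpolated with a
  *centripetal Catmull–Rom* spline. Annotators place points *on* the
  trichome, so the curve must pass through every control point; the
  centripetal parameterisation does that without overshoot or cusps. Two
  control points degenerate to a straight segment.
* **Coordinate convention** (used everywhere): continuous 0-based
  `(row, col)` coordinates with pixel centers at integer positions.
  Rescaling an annotation from $(H,W)$ to $(H',W')$ multiplies rows by
  $H'/H$ and columns by $W'/W$. Points may lie up to 5% outside the image
  (edge trichomes); the rasterizer clips.
* **Rasterization.** The curve is sampled at ≥ 2 samples per pixel of arc
  length and drawn with a disc brush of diameter `stroke_width`: a pixel
  is painted when its center lies within `stroke_width/2` of a curve
  sample (the nearest pixel to each sample is always painted, so
  single-pixel strokes stay 8-connected). The default `stroke_width` of
  2 px at the working resolution reflects how wide trichomes appear
  there; it is configurable because the original annotation tooling's
  rendering width is not documented anywhere we could consult.
* **Sparse storage.** Masks are kept as `(row, col)` foreground index
  sets (`sparse_mask`), proportional to foreground size; dense/sparse
  round trips are exact and property-tested.

A midvein-overlap convention travels with the data: annotators do not
trace trichomes that lie entirely on the bright midvein (white hair on
white vein is unreliable), so the synthetic generator never places a
ground-truth hair wholly inside its midvein band, and the toolkit does
not post-filter predictions.

## Augmentation: geometry before raster

The augmentation recipes are the compact strings used in the
model-selection study: `RS<n>` (resize to n×n), `RC<n>` (random n×n
crop), `RF` (random flip), composed with `+` and honoured in token order.
The invariant that matters is *geometry before raster*: every geometric
step transforms the image and the spline coordinates, and the mask is
rasterized once, at the final geometry. Masks are never interpolated.
The test suite demonstrates the artifact this avoids by comparing against
a deliberately wrong oracle (nearest-neighbour mask downscaling), which
fragments long hairs into extra connected components.

Two reading decisions were open:

* "Combined random vertical and horizontal flip" is read as two
  independent Bernoulli(0.5) coin flips, which generates all four
  orientations.
* Crop placement is uniform over valid top-left corners, and splines are
  clipped in *continuous* coordinates at the crop border (the densely
  sampled curve is split into maximal inside runs), keeping partial edge
  trichomes just as human annotators do.

## The segmentation network

The segmenter is modular: any registered feature extractor composes with
any registered segmentation head. The registry carries the six full-size
encoder families evaluated in the field (`vgg19bn`, `resnet18`,
`resnet50`, `se_resnet50`, `regnetx064`, `effnet_b5`) plus the five
decoder families (`unet`, `unetpp`, `deeplabv3`, `linknet`, `manet`), and
a seventh encoder, `tiny` (three convolution blocks, stride 4), added so
the full train/evaluate/rank pipeline runs in seconds to minutes on one
CPU.

There is no deep-learning backend in this stack, so the network is
implemented natively: a small reverse-mode autodiff tape over `H×W×C`
arrays, with im2col/col2im convolution kernels in C++ and BLAS matrix
products. Every encoder–decoder–loss combination is verified against
finite-difference gradients in the test suite. Three implementation
choices deserve a caveat:

* Grouped and depthwise convolutions (RegNetX, EfficientNet) are realised
  as dense convolutions, and EfficientNet-B5's seven MBConv stages are
  folded into four SE-bottleneck stages of B5-like widths. These two
  encoders are architecture-shaped stand-ins, kept name-compatible for
  scale-up, not faithful reimplementations.
* No ImageNet-pretrained weights are bundled (`pretrained = TRUE`
  errors); encoders initialise with He-normal weights under the config
  seed. Inputs are standardised by per-dataset channel statistics
  computed from the training set.
* Batch normalisation at batch size one degenerates to per-image spatial
  (instance) normalisation and is implemented as such in both training
  and evaluation, which makes the forward pass deterministic per image.

**Losses.** Four surrogates for the binary objective, all on the
probability map $p$ against the binary target $g$: mean binary
cross-entropy; soft Dice loss $1-(2\sum pg+\varepsilon)/(\sum p+\sum
g+\varepsilon)$; soft Jaccard loss $1-(\sum pg+\varepsilon)/(\sum p+\sum
g-\sum pg+\varepsilon)$; and focal loss $-\frac1N\sum(1-p_t)^\gamma\log
p_t$ with $\gamma=2$, unweighted. The smoothing constant is
$\varepsilon=1$; the sources name the losses without constants, and these
are the conventional defaults. For binary predictions Dice and Jaccard
are linked by $J = D/(2-D)$ up to $O(\varepsilon/|mask|)$, which the
suite asserts.

**Training protocol.** Adam at learning rate $10^{-3}$ with no schedule,
early stopping on validation IoU with patience 5, best checkpoint by
validation IoU — the optimiser, schedule, epochs and batch size are
unreported in the source study, so these are declared package defaults,
visible in `model_config()`. Gradient accumulation over 2 images is the
default batch; together with initialising the segmentation head bias at
the background prior (−3, the standard sparse-foreground initialisation)
it was chosen in a pilot on the frozen fixture seed so the desk-scale
recovery run converges within a CPU budget. Augmentation applies to the
training stream only; validation images are resized (RS) to the recipe's
final size with masks rasterized there. Binarization threshold defaults
to 0.5 and is configurable. Training is exactly reproducible given the
config seed (single CPU, deterministic kernels); the repeat-run "mean ±
range" reporting protocol of the grid module therefore shows zero range
for identical seeds and small ranges across derived repeat seeds.

## The synthetic world

`synthleaf` generates the world the pipeline is tested in: a green
textured background (base RGB around (0.36, 0.47, 0.28), Gaussian grain
plus low-frequency blotch, radial vignette), a bright *horizontal*
midvein band (the midvein always crosses the field of view left to
right), and thin bright curvilinear hairs. Hairs are brighter than the
background, as white trichomes on a green leaf are. Counts are negative
binomial per image (configurable mean 0–120, dispersion 8), lengths and
widths gamma with means 48 px and 1.6 px at the default 256×256
resolution, and curvature bounds the perpendicular deviation at 15% of
hair length. Endpoints are uniform; mid control points are displaced
perpendicular to the chord; hairs wholly inside the midvein band are
rejected (the annotation convention); draw order is randomised. Each
image's seed is derived by hashing (panel seed, genotype, index), so
records are deterministic independent of generation order.

The default five-genotype panel spans hair-count means 0, 15, 35, 70 and
110 with nominal classes "1", "3", "4", "4+" and "5" — a desk-scale
stand-in for a real genotype panel spanning the hairiness gamut.

What the generator does *not* emulate, and hence what a green test does
not establish: real leaf venation and specular reflection, annotator
noise (missed or mis-traced hairs), the tangled-hair saturation of the
hairiest class ("5+", which humans could not confidently annotate
either), or domain transfer between seasons and environments. Green
acceptance here means the pipeline recovers planted structure in its own
stated world, not that it reproduces published full-scale accuracy, which
requires the deposited image corpora and GPU-scale training of the
full-size models and is explicitly out of scope.

## Quantification conventions

* IoU of two empty masks is defined as 1.0 (perfect agreement); an empty
  prediction has precision 0 and an empty ground truth recall 0, each
  with a warning; F1 is 0 when both components are 0.
* Per-genotype ranking uses the arithmetic mean LTS by default (the
  median is exposed as an option); ties are broken by genotype name so
  rankings are stable across runs.
* Rank agreement is Spearman's rho with average ranks for ties.
* `flag_ghs_dips()` reports adjacent ordinal classes whose mean LTS
  decreases — the tooling for noticing that an ordinal breeder scale need
  not be monotone in measured trichome density (the characteristic dip at
  class "4"). It is asserted on constructed tables only; no claim is made
  about real data.

## Numerical and degenerate-input choices

* Split arithmetic is floor/floor/remainder: at $N=1250$ and 65/15/20
  this gives 812/187/251. Stratified splitting applies the same rule per
  stratum (±1 record per stratum); strata under 3 records go wholly to
  train with a warning. Whether the original split was stratified is not
  documented; both paths are provided.
* Rounding is half-to-even (base `round`), which is symmetric and keeps
  rasterization exactly flip-equivariant.
* Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ inside log-losses.
* Seeds derive from a 31-bit Lehmer-style hash (`derive_seed`), keeping
  every derived seed a valid 32-bit R integer.

## Known limitations

Pure-CPU training limits practical image sizes and model widths; the
full-size encoders are constructible and train correctly but are not
practical beyond small inputs in this implementation. The LTS measures
pixel fraction only: genotypes trading hair count against hair length can
tie. The generator's hairs are single-curve structures without branching
or crossing-induced brightness saturation.
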