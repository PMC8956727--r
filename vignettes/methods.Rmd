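---
title: "How petrigen builds synthetic colony-counting datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How petrigen builds synthetic colony-counting datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Training an instance-segmentation detector to localize, segment and count
microbial colonies (colony-forming units) on agar plates normally requires
thousands of dish photographs with per-colony annotations — expensive to
collect and tedious to label. `petrigen` implements a cut-and-paste
alternative: starting from a *small* set of annotated dish images plus a
few empty dishes, it extracts real colony clusters with classical computer
vision, composes them onto empty-dish backgrounds with pixel-exact
bounding boxes and instance masks, and optionally re-styles the composites
with a one-shot neural style transfer stage so the pasted edges and
lighting statistics look like real photographs.

The package covers five working species labels
(`r paste(petrigen::agar_species(), collapse = ", ")`), a closed set that
can be reconfigured.

## Colony clustering

Colonies on crowded plates overlap. Cutting one colony at a time would
destroy the geometry of touching colonies, so overlapping colonies are
extracted as one *cluster*. Two colonies are linked when their bounding
boxes overlap by strictly more than a threshold fraction (default 0.01)
of the **smaller** box's area; clusters are the connected components of
that graph, found by breadth-first search. Using the smaller area as the
denominator keeps the relation symmetric and links a pair as soon as
either colony loses more than 1% of itself to the other; the alternative
reading (each box's own area, then symmetrized) differs only for extreme
aspect-ratio pairs. Components are returned sorted by smallest member so
all downstream sampling is reproducible.

## Cluster extraction

Each cluster is cut out as the union bounding rectangle of its boxes plus
a margin (default 4 px). The cutout's opacity (alpha) channel is the
element-wise (Hadamard) product of three masks:

* `m_bx` — 1 on the union of the member bounding boxes, 0 elsewhere. This
  guarantees that nothing outside the annotated boxes can ever be pasted.
* `m_s` — a binary colony segmentation. The fragment is first
  unsharp-masked (Gaussian sigma 2 px, amount 1), dark substrate
  artifacts (printed text, contamination) are removed, speckle is
  denoised, and the luminance channel is segmented with the Chan–Vese
  active-contour-without-edges model. The result is dilated (default
  2 px) so colony edges are kept.
* `m_b` — a blending mask in [0, 255] proportional to each pixel's
  Euclidean CIELab distance to the mean background color (mean over
  pixels outside `m_s`), normalized by the fragment maximum. Pixels that
  look like agar get low opacity, so pasted cutouts melt into new
  backgrounds instead of carrying a rectangular halo.

`alpha = m_bx ∘ m_s ∘ m_b`. Per-colony instance masks are `alpha > 0`
restricted to each colony's box; a cluster whose alpha is entirely zero is
rejected and never enters the cutout bank.

### Dark-artifact removal

Dark objects are detected in CIELab: a pixel is a candidate when
`L* < 40` (lightness scale 0–100) or `b* < -5` (dark bluish ink has
negative b*). Both thresholds are absolute and user-tunable; the defaults
were chosen for typical back-lit agar plates, where the substrate sits
far above `L* = 40`. The candidate mask is dilated (default 2 px) and
every masked pixel is replaced by the value of the first valid pixel
reached by a seeded uniform 8-neighborhood random walk over the *frozen*
input image (donors are never already-replaced pixels, so the result is
independent of pixel visiting order). Walks are capped at 10× the
fragment perimeter; a capped walk falls back to the nearest valid pixel
by Euclidean distance. Replacement produces speckle, which the next stage
removes with non-local-means denoising (strength 8, patch 3, search
window 9; strength 0 is the identity).

### Chan–Vese details

The level set is evolved with the standard semi-implicit scheme (the
curvature term's neighbor weights are computed from one-sided gradients
and moved to the denominator), checkerboard initialization of period
10 px, smoothed-delta step `dt = 0.5`, and a cap of `cv_max_iter`
(default 200) iterations; iteration stops early once fewer than 0.1% of
pixels change phase for three consecutive iterations. Because the model
is contrast-agnostic, the foreground phase is chosen as the one whose
mean luminance differs more from the fragment-border mean (the border is
assumed to be substrate — guaranteed by the cutout margin). A constant
fragment has no separable phases and yields an empty mask with a warning.

## Patch composition

Synthetic patches (default 512×512 px, the tile size detectors are
trained on) are built as follows:

1. Pick one empty dish, rotate the whole image by a uniform random angle
   (bilinear interpolation) and crop a uniformly random window containing
   no out-of-bounds fill.
2. Pick one species per patch, as on real single-culture plates.
3. Draw a target colony count from an exponential law with mean 10
   (`count_mean`, the observed mean colonies per patch on real plates),
   rounded half-up with zero allowed — empty patches exist in reality.
4. Draw cutouts of that species with replacement; for each, sample a
   rotation in [0, 360), independent horizontal/vertical flips and a
   uniform position, and accept the first proposal (up to
   `max_place_attempts = 50`) whose footprint — transformed `alpha > 0`,
   dilated by 1 px — lies fully inside the patch and is disjoint from all
   previous footprints. Placement repeats until the cumulative colony
   count reaches the target (a multi-colony cluster may overshoot; the
   actual count is recorded) or a budget of 10 cluster draws per target
   colony is exhausted.
5. Composite with the standard alpha-over blend; rotation is applied to
   RGB and alpha jointly with premultiplied-alpha interpolation so no
   background color bleeds through the edge.
6. Recompute every instance's bounding box as the tight box of its
   transformed mask. A colony keeping less than 30% of its mask (only
   possible under explicit clipping) is dropped and erased.

The overlap test runs on alpha footprints rather than boxes because the
boxes of overlapping-cluster cutouts are loose and would over-reject.
Optional size augmentation (`allow_scaling`, off by default) scales each
cutout by a uniform factor in [0.8, 1.25].

Every patch's RNG seed is derived from `(master seed, patch index)` by a
counter scheme, so any single patch can be regenerated alone and two runs
with the same `(seed, config)` produce byte-identical annotations.

## Neural stylization

Raw composites have slightly wrong edge statistics and homogeneous
lighting. A one-shot style transfer stage fixes both: a small
image-generation network `g` is trained per (content tile, style image)
pair to minimize

$$
\mathcal{L}(y, y_c, y_s) = (1-\lambda)\sum_\ell \lVert G_\ell(y)-G_\ell(y_c)\rVert_F^2
+ \lambda \sum_\ell \lVert G_\ell(y)-G_\ell(y_s)\rVert_F^2,
$$

where `y = g(y_c)`, the `G_ℓ` are Gram matrices
(`G = F Fᵀ / (C·H·W)`) of feature maps tapped at five successive blocks
of a frozen convolutional feature extractor, and λ mixes content against
style: λ = 0.02 gives a *semi-stylized* set, λ = 0.05 a *fully-stylized*
set. Pushing λ beyond 0.05 visibly erodes species-specific colony
appearance, so `validate_config()` warns (but does not refuse) above it.
Both the content and the style term use Gram statistics; a raw
feature-matching content term (the common perceptual-loss convention) is
available behind `content_gram = FALSE`.

Three numerical choices matter:

* **Squared Frobenius norms.** With unsquared norms and λ < 1/2 the
  content optimum `y = y_c` is a local minimum of `L` (the content term
  grows linearly in every direction with weight 1−λ while the style term
  can fall at most linearly with weight λ), so gradient descent from an
  identity-initialized generator is impossible. The squared norm — the
  standard Gram-loss convention — removes the kink and restores descent.
  We verified this numerically before adopting it: with unsquared norms,
  analytic gradients matched finite differences to 1e−10 yet the loss
  rose for every tested learning rate.
* **Identity initialization.** The generator is parameterized as
  `y = x + residual` with a zero-initialized output convolution, so an
  untrained network is exactly the identity. This stabilizes warm starts:
  stylizing successive tiles of one style re-uses the previous weights,
  which starts at or below the cold-start loss and converges faster.
* **Fixed random feature extractor.** The extractor is a frozen, seeded
  He-initialized pyramid of five 3×3 conv + ReLU blocks (8, 16, 16, 16,
  16 channels) separated by 2× average pooling. Random shallow
  convolutional features are a serviceable basis for Gram-type style
  statistics at this scale, and a fixed seed makes every loss value
  reproducible across sessions. The extractor is never trained.

Training is plain SGD (default learning rate 1e−4, chosen as the largest
rate stable across content/style pairs at the quartic Gram objective;
200 iterations by default). Patches are stylized four at a time as one
2×2 tile (1024×1024 for 512-px patches) for throughput, with 20 style
fragments cycled round-robin and per-style warm starts. Stylization is
geometry-preserving: annotations and masks are copied unchanged.

Two generator architectures are provided: `highres` (default), a small
multi-resolution network that maintains a full-resolution branch with
cross-resolution fusion, in the spirit of high-resolution representation
networks; and `light`, a 3-level residual fully-convolutional net used
for CPU-scale tests.

## The 13-parameter configuration surface

`gen_config()` exposes exactly 13 tunable stage parameters — clustering
threshold (1); unsharp radius/amount (2); CIELab L*/b* thresholds (2);
artifact-mask dilation radius (1); NLM strength/patch (2); Chan–Vese
mu/max-iterations (2); segmentation-mask dilation radius (1); blending
gamma (1); style weight λ (1). The blending stage's single knob is a
gamma exponent on the normalized CIELab distance (1 = plain
proportionality), our choice for the one tunable that stage carries.
Everything else (patch size, seeds, counts, architectures) is structural.
`validate_config()` enforces ranges and the inventory;
`config_inventory()` prints it.

## The fixture generator

`make_empty_dish()` / `make_annotated_dish()` render pseudo-real dishes so
the entire pipeline builds and tests with zero external data: a bright
agar disk with a darker rim on a dark surround, a linear lighting ramp of
random direction (relative amplitude 0.15), Gaussian pixel noise
(sigma 2), and soft-edged anisotropic colonies rendered as
3-level-thresholded Gaussians with species-specific palettes and blur
(sharp small golden *S. aureus* at one extreme, large blurred greenish
*P. aeruginosa* at the other — mirroring which species are easy and hard
to segment on real plates). One species per dish, as on real
single-culture plates. Bounding-box overlap between chosen pairs is
forced with probability `overlap_probability` to exercise the clustering
path, and dark text-like strokes (L* < 30) are stamped on the substrate
to exercise artifact removal. Exact ground-truth masks are returned.

The default dish diameter (760 px) puts colonies at 7–14 px radius — the
scale colonies have when a full-plate photograph is tiled into 512-px
patches. The radius range was set together with the 2-px segmentation
dilation: with much smaller colonies the fixed dilation margin alone
would cap the achievable mask IoU below the 0.8 working target,
independent of segmentation quality.

What the fixtures deliberately do **not** emulate: real agar texture,
condensation, reflections, camera noise statistics, and inter-species
color ambiguity. Passing the fixture-based tests therefore demonstrates
the correctness of the geometry, bookkeeping and algorithm chain — not
photometric performance on real plates, which depends on tuning the 13
stage parameters to the actual imaging setup.

## Problem sizes used in the test-suite and checks

The shipped tests run the full chain at reduced sizes chosen to exercise
every code path with comfortable margins: extraction quality is measured
on 50 generated dishes (IoU ≥ 0.8 against fixture ground truth,
Chan–Vese disk oracle at IoU ≥ 0.95), mask algebra on 50 extracted
cutouts, determinism on two 100-patch runs at 64 px, the count law on
100,000 draws, and stylization descent on 64-px tiles with the `light`
generator. The 512-px patch and 1024-px tile geometry contracts are
checked at full size.

## Known limitations

* Whole-dish (≈4000×4000) synthesis is out of scope; the method composes
  individual patches.
* The sMAPE definition uses the symmetric denominator `(p+t)/2` with the
  0/0 term defined as 0; upstream benchmark supplements sometimes use
  `max(p, t)` — documented as an assumption.
* Annotation input is a simple JSON dialect (colony list with `x`, `y`,
  `width`, `height`, species); other dialects are accommodated by a
  field-name mapping, not by format sniffing.
* Input images are read as PNG; convert other formats before ingestion.
* No GAN-based generation and no multi-style interpolation, by design.
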