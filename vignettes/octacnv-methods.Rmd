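---
title: "Methods: CNV segmentation and activity grading in OCTA en-face images"
author: "octacnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV segmentation and activity grading in OCTA en-face images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octacnv)
```

## The clinical problem

Choroidal neovascularization (CNV) — abnormal vessel growth from the
choroid — is graded on OCT angiography by five morphological activity
criteria: a well-defined (lacy-wheel or sea-fan) **shape** as opposed to long
filamentous vessels; numerous tiny **branching** capillaries;
**anastomoses and loops**; a **peripheral arcade** connecting the vessel
termini (versus a "dead tree" appearance); and a perilesional hypointense
**dark halo** on the choriocapillaris slab. A lesion presenting at least
three of the five criteria is graded *active*
(`activityScore()`). The package automates this grading from a pair of
co-registered en-face projections: the outer-retina slab, where the CNV
network is visible, and the choriocapillaris slab, where the halo is.

The pipeline has two blocks:

1. **Segmentation.** A parameter-reduced U-Net (`buildSegCNV()`) trained
   with soft Dice loss predicts the CNV mask on the outer-retina image.
   Multiplying mask and image gives the lesion ROI (`makeROI()`). Two
   classical algorithms derive the remaining region inputs: `segPA()`
   extracts the inter-vessel spaces at the lesion margin and `segDH()`
   grows the dark halo on the enhanced choriocapillaris image.
2. **Classification.** Five binary heads grade the criteria: four
   transfer-learning heads on a VGG16 convolutional backbone
   (`buildTransferHead()`) and, for the peripheral arcade, a small network
   trained from scratch (`buildScratchNet()`). Head routing follows
   `classifierTable()`: the shape/branch/loops heads read the CNV ROI, the
   arcade head the arcade mask, the halo head the halo mask.

Evaluation uses subject-wise nested cross-validation (`nestedCVSplit()`):
folds are split by subject so that two images of one patient can never sit
on opposite sides of a split, and inner folds are available for
hyperparameter selection. `runPipeline()` drives the whole loop.

## The segmentation network

The reference architecture is an encoder–decoder with skip connections,
two 3×3 convolutions + ReLU per level, 2×2 max pooling, nearest-neighbour
upsampling followed by convolution, dropout (p = 0.25) on the two deepest
blocks, and a final 1×1 convolution + sigmoid. Only the total budget —
about 1.6 million trainable parameters for 128×128×1 input — constrains the
channel counts, so the package fixes and documents one concrete
configuration: encoder widths (16, 32, 64, 128) and bottleneck width 192.
A bottleneck of 256 with this decoder would land near 1.92 M; shrinking
that one width to 192 brings the exact layer-wise total to

```{r}
m <- buildSegCNV(128, 128)
m$spec$trainable_parameter_count
round(m$spec$trainable_parameter_count / 1e6, 1)
```

i.e. 1,556,705 parameters, inside the intended 1.55–1.65 M band. The
network is fully convolutional, so the count does not depend on the input
size; any height/width divisible by 16 builds.

Training minimizes the smoothed soft Dice loss
$L = 1 - (2\sum p g + \varepsilon)/(\sum p + \sum g + \varepsilon)$ with
$\varepsilon = 10^{-6}$ (avoids 0/0 on empty masks). Prediction thresholds
the per-pixel probability at 0.5 with **ties counted as foreground**, and
restores the original resolution by nearest-neighbour upsampling.

Optimization uses Adam with batch 8. The default learning rate is
3×10⁻⁴: at 10⁻³ the Dice-loss U-Net reproducibly collapses to the empty
mask on phantom data (the loss saturates at 1 once the ReLUs die), while
3×10⁻⁴ trains stably. A small grid-search helper (`gridSearchHyper()`)
over learning rate × batch size mirrors how such settings are selected in
practice; all stochastic stages (initialization, shuffling, dropout,
augmentation) consume a single experiment seed.

## The classifier heads

The VGG16 backbone is the canonical 13-convolution stack; with its
original three fully connected layers and 1000-class output it totals
138,357,544 parameters (`vgg16LayerTable()`), the familiar "138 million".
For transfer learning the fully connected stack is replaced by a new head —
global average pool (512) → dense 419 → dense 1012 → dense 1 + sigmoid —
whose trainable total is exactly

$$513\cdot419 + 420\cdot1012 + 1013 = 641{,}000.$$

The published budget ("around 641,000") pins the head size but not its
internal layout; this reconstruction is recorded as the package's own and
is asserted in the tests. The freeze policy per criterion: branch and dark
halo train the head only; shape additionally unfreezes the **last three**
backbone convolutions; anastomoses/loops the **last one** ("3Conv"/"1Conv"
read as the deepest convolutions, the usual fine-tuning convention). Note
that a single deepest VGG convolution alone holds ~2.4 M parameters, so the
641,000 figure can only describe the FC-only configurations; the package
treats it that way. Because the head pools globally, the backbone accepts
any input side divisible by 32; 224 is the default used for real work,
while the tests exercise 32 px inputs for speed.

Pretrained ImageNet weights are optional (`backboneWeights` takes an RDS
file of conv parameter sets). Without them the backbone is seeded random:
the reproducible content — architecture, freeze policy, parameter counts,
training mechanics — does not depend on the external weight artifact, and
the test suite runs fully offline. Freezing is literal: after training,
frozen layers are bit-identical to their initial values.

The peripheral-arcade head is trained from scratch: four 3×3 conv + ReLU +
2×2 pool blocks (widths 16–128), flatten, one dense sigmoid unit; every
parameter trainable. Heads train with binary cross-entropy and Adam
(defaults: 10⁻⁴ transfer, 10⁻³ scratch), with random augmentation on by
default.

Augmentation draws rotation (≤ ±25°), zoom (0.8–1.2), horizontal/vertical
flips and shear (≤ ±10°) and warps about the image centre with an
inverse-mapped affine transform (bilinear for images, nearest for masks;
out-of-domain pixels are 0). The warp is implemented in the package so its
coordinate convention is exact and testable: a 90° rotation moves a pixel
at offset $(x, y)$ to $(-y, x)$ with y pointing down. Labels always pass
through unchanged, and an identity configuration returns the image
bit-unchanged.

## Classical extraction of arcade and halo

The published description names the steps but none of the operational
constants; the package fixes them once (in `morphoParams()`), exposes every
one, and freezes the defaults after verifying them on phantoms:

* **Vessel binarization**: a pixel is a vessel iff its intensity strictly
  exceeds the truncated-window local mean (window 15) minus 0.05 × the
  local range; evaluated inside the dilated CNV mask only. Strictness
  carries a 10⁻⁹ guard so constant regions never binarize to vessels.
* **Ring mask**: dilation minus erosion with disk elements of radius 5 (at
  the 304-px reference scale, rescaled proportionally), i.e. a band
  *straddling* the lesion boundary — arcade structures sit on the margin
  itself, not strictly outside it. The disk of radius r contains pixels at
  Euclidean distance ≤ r + 0.5, so radius 1 is the full 8-neighbourhood.
* **SEG-PA** composes the three primitives: binarize, invert within the
  (dilated) mask so inter-vessel spaces become foreground, multiply by the
  ring.
* **SEG-DH**: contrast-limited adaptive histogram equalization (8×8 tiles,
  clip limit 2.0, via EBImage) enhances the choriocapillaris image; the
  CNV-mask contour offset one pixel outward (8-connected contour, the halo
  being perilesional) seeds region growing; the grown region is clipped to
  an annular search region (outer radius 30 at reference scale), to the
  outside of the lesion, and to hypointense pixels (below the median
  enhanced intensity minus 0.05) — the halo is by definition dark, and
  this keeps a featureless bright field from growing into a spurious halo.
* **Region growing** is 4-connected with a FIFO queue, seeds and
  neighbours in row-major order, each pixel examined once; a candidate is
  accepted when it differs from the running mean of the accepted region by
  at most the tolerance (default 0.15). A fixed-seed-mean variant is kept
  because it admits an exhaustive flood-fill oracle; the running mean is
  the default because the halo's intensity drifts with distance from the
  lesion. The acceptance comparison carries a 10⁻¹² guard so tolerance 0
  grows exactly the equal-intensity connected component despite
  accumulation rounding.

All morphology is pure and deterministic, and each primitive is tested
against an independent brute-force implementation on fixtures up to 64×64.

## The phantom generator

No clinical images ship with the package; a synthetic phantom
(`generatePhantomPair()`, `generatePhantomDataset()`) emulates the study
material: 6×6 mm² en-face pairs sampled at 304×304 (default), a central
lesion, and a cohort in which some subjects contribute two images. Each
activity feature is an independent toggle with an exactly known support:

* the base lesion is `nSpokes` straight radial vessels, rasterized with
  Bresenham lines and thickened by disk dilation, so every ground-truth
  pixel count is analytic; with the shape toggle off these sparse radial
  strands *are* the filamentous (label 0) presentation — a deliberate
  simplification that keeps the skeleton countable;
* shape on adds interior haze and a dense marginal fringe (compact
  sea-fan); loops adds circumferential arcs at mid-radius; branch adds
  short high-curvature twigs (the only stochastic skeleton component);
  peripheral arcade adds a near-closed marginal arc with four gaps;
* the dark halo multiplies the choriocapillaris texture by 0.5 inside an
  annulus of width 12 px around the lesion;
* background capillary texture is band-pass (difference-of-Gaussians)
  noise with amplitude at most 0.25 of the vessel intensity, so
  lesion/background separability exists by construction; additive Gaussian
  noise (σ = 0.03) tops off both channels.

Randomness is split into fixed per-component sub-streams derived from one
seed, which yields two properties the tests rely on: bit-identical
regeneration, and toggle locality (flipping one feature changes pixels only
inside that feature's support). Datasets add per-subject effects — an
intensity gain in [0.9, 1.1] and a lesion-radius factor in [0.85, 1.15] —
so subject-wise cross-validation genuinely differs from image-wise, plus
small centre jitter and i.i.d. per-feature labels at configurable
prevalence.

Defaults (radius 60 px ≈ 1.2 mm at 6 mm/304 px, vessel width 3 px, 10
spokes, halo contrast 0.5) are plausibility choices — the source material
reports no quantitative lesion morphometry — made once and not revisited.
The phantom does **not** model OCTA speckle/decorrelation statistics,
projection artefacts, vessel-calibre distributions or 3-D structure, so
passing recovery tests demonstrates that the implementation learns and
extracts the intended structures under controlled conditions, not clinical
performance.

## Metrics and scoring

`diceCoefficient()` implements $2TP/(2TP+FP+FN)$ on pixels (1.0 when both
masks are empty: perfect agreement on absence); it equals $1 -$
`diceLoss()` on binary inputs and equals the F1 of the pixel-level
confusion. `classificationMetrics()` implements accuracy, F1, specificity
and sensitivity from the 2×2 confusion table; a zero denominator yields
NaN with a warning rather than a silent 0, which would corrupt fold
averages. Fold aggregation keeps the full per-fold Dice distribution (for
violin-style reporting) alongside unweighted fold means and medians.
Prevalence tables round half-up to two decimals. The activity rule is the
monotone threshold: active ⇔ at least 3 of 5 criteria present.

## Problem sizes used by the test suite

The recovery experiments are sized for a single CPU: segmentation trains
on 50 phantom pairs at 128×128 for 6 epochs with 10 pairs held out
(the suite checks held-out mean Dice ≥ 0.80); halo recovery runs one
native 304×304 phantom at default parameters (Dice ≥ 0.7); the arcade head
trains on 40 SEG-PA masks for 40 epochs with rotation/flip-only
augmentation — the arcade signature is rotation- and flip-symmetric, while
zoom and shear distort the thin marginal ring — against a shuffled-label
control (held-out accuracy ≥ 0.8 vs. chance). End-to-end pipeline tests
run at 64-px phantoms with 32-px network inputs and a few epochs: they
verify structure, composition and reproducibility, not accuracy.

## Known limitations

* The CNN engine is deliberately compact (single-image batches accumulated
  in R, im2col convolutions in C++); it is sized for the package's
  networks, not for general deep learning.
* Transfer heads start from seeded random backbones unless ImageNet
  weights are supplied; random-backbone transfer heads are weaker
  classifiers, which the pipeline tests account for by testing structure
  rather than accuracy.
* The phantom's simplifications (above) mean thresholds verified here do
  not transfer to clinical data; the published clinical accuracies are not
  reproduction targets since that dataset is private.
* Bilinear resizing of very small masks can erase one-pixel structures;
  the pipeline therefore keeps masks nearest-neighbour throughout.
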