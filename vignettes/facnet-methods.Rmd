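---
title: "FAC-Net: model, design choices, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAC-Net: model, design choices, and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation problem

Dermoscopy images of skin lesions are hard to segment automatically: lesion
boundaries are irregular and fuzzy, the contrast between lesion and
surrounding skin can be small, and hairs and immersion-fluid bubbles occlude
both regions. `facnet` implements FAC-Net, an encoder-decoder convolutional
network for this task, together with its training objective, evaluation
protocol, dataset handling, ablation harness, and a synthetic data generator
that makes the whole pipeline testable without any challenge dataset.

## Architecture

The backbone follows the CE-Net pattern. A stride-2 stem convolution is
followed by four residual encoder stages with channel widths $C, 2C, 4C, 8C$
(default $C = 64$) at spatial resolutions $H/4, H/8, H/16, H/32$; each stage
is a strided residual block followed by an identity residual block, with
batch normalization throughout. The bottleneck applies a dense-atrous context
block (four cascaded branches with dilation rates 1/3/5) and residual
multi-kernel max pooling (kernels 2/3/5/6, each reduced to one channel by a
1x1 convolution and bilinearly upsampled back), appending four context
channels. The decoder mirrors the encoder with 1x1-reduce /
transposed-conv-upsample / 1x1-expand blocks; each level concatenates the
matching skip feature and fuses it with a 3x3 convolution; a final
transposed-convolution block restores full resolution before a 1x1
convolution and a logistic map yield the per-pixel lesion probability.
Inputs must be divisible by 32 along both axes.

Two additions define FAC-Net:

* **Feedback Fusion Block (FFB)** — one per adjacent encoder pair (stage 1,2),
  (2,3), (3,4). The deeper map $N \in \mathbb{R}^{2C' \times H'/2 \times
  W'/2}$ is reduced by global **max** pooling, projected by a 1x1 convolution
  to $C'$ channels and squashed to $[0,1]$; this per-channel weight gates a
  3x3 convolution of the shallower map $M$. The gated map is concatenated
  with the original $M$, the bilinearly upsampled $N$ is concatenated on top,
  and a 1x1 convolution restores $C'$ channels. The result **replaces** the
  raw encoder feature on the skip connection.
* **Attention Mechanism Block (AMB)** — after each decoder skip fusion,
  channel attention (squeeze-excite: global average pool, $C \to C/r \to C$
  bottleneck, logistic) is followed in series by a spatial attention whose
  per-position statistics across channels are the maximum, the mean, and a
  quantized **mode**; the three maps are summed element-wise, normalized by a
  softmax over all positions into $W_P$, and applied residually:
  $A'' = A' + W_P \odot A'$.

The channel mode at a position quantizes the $C$ channel values into `bins`
equal-width intervals spanning that position's own $[\min, \max]$ range and
returns the midpoint of the most populated interval (ties toward the smaller
midpoint; a degenerate range returns the common value). A mode of continuous
activations is undefined without quantization, so the bin count is an
explicit parameter (default 32). The statistic is piecewise constant, hence
non-differentiable almost everywhere; it is treated as a constant during
backpropagation, which the test suite verifies.

## Training objective and optimization

Training minimizes the soft Dice loss
$L = 1 - \frac{2\sum_i y_i p_i + \varepsilon}{\sum_i y_i + \sum_i p_i +
\varepsilon}$ over all pixels of a batch, with $\varepsilon = 1$ so the
all-empty case is defined (the evaluation metrics stay literal, without
smoothing). Optimization uses Adam at learning rate $10^{-4}$, batch size 12,
200 epochs by default, with Kaiming-normal initialization of all
convolutions — the recipe the network was designed around. No augmentation,
no learning-rate schedule, no pretrained encoder. When a validation split is
given, the checkpoint with the best validation Jaccard is kept; that choice
is recorded in the fit object, since selecting the final epoch instead is
equally defensible when training to convergence.

## Evaluation protocol

Predictions are binarized at 0.5 (a convention; the value is a parameter).
Six metrics are computed from pixel confusion counts: accuracy, sensitivity,
specificity, precision, Jaccard and Dice. A metric whose denominator is zero
is reported as `NA` and skipped in averages rather than raising an error.
Reports aggregate two ways: the per-image arithmetic mean (the
ISIC-challenge convention, used as the headline) and pooled counts over all
pixels; both are returned because published tables rarely state which was
used, and the two can differ noticeably when lesion sizes vary.

Dataset splits follow the challenge protocols: the 2018 set's 2594 annotated
training images are shuffled and partitioned 70/10/20% into train/val/test
(floor for the earlier parts, remainder to the last); the 2017 (2000 train /
600 test) and 2016 (900 / 379) sets keep their training images for training
and split their test images 1:4 into val:test. The shuffle seed (default 42)
is recorded in the split object and its manifest. Whether the original
experiments stratified by lesion type is unknown; no stratification is
applied.

## The synthetic generator

`synth_generate()` emulates the failure modes that make dermoscopy hard:
one star-convex lesion whose contour radius is modulated by a random
harmonic series of order up to 8 (bounded at 35% relative amplitude) for
irregular outlines; a configurable lesion/skin `contrast` in $(0,1]$; a
Gaussian-blurred boundary (`boundary_blur_sigma`, pixels) for fuzzy edges;
dark quadratic hair strokes 1-3 px wide; bright bubble rings; low-frequency
background shading and additive Gaussian noise. The mask is the unblurred
contour, so the ground truth stays binary and single-component. Everything
is reproducible from one seed.

Defaults (radius 15-35% of the side, blur 1.5 px, contrast 0.5, up to 4
hairs and 3 bubbles, noise 0.02) are chosen to look like a mid-difficulty
dermoscopy crop. Decreasing `contrast` strictly decreases Otsu-style
separability, giving a monotone difficulty knob that the tests check. What
the generator does **not** emulate: multi-lesion images, color constancy and
illumination casts, vignetting, ruler markings, gel interfaces, and the
full texture statistics of real skin. Passing the synthetic benchmark
therefore demonstrates that the architecture, loss, optimizer and metrics
are implemented correctly and can learn a nontrivial boundary — it does not
certify clinical-grade accuracy on real dermoscopy.

## Numerical and design choices

* **Compute core.** The package carries its own dense tensor engine:
  reverse-mode autodiff over 4-d arrays with im2col + GEMM convolutions in
  C++ (RcppArmadillo), transposed convolutions as the exact adjoint of the
  strided convolution, and analytic backward passes for pooling, bilinear
  resizing, batch normalization and the spatial softmax. Every operator is
  validated against central finite differences in the test suite.
* **FFB pooling.** The deep-branch reduction is global max pooling; global
  average pooling is available by configuration for sensitivity checks. The
  gate is squashed through a logistic by default — an unbounded
  multiplicative gate destabilizes training — with a raw-linear option.
* **Concatenation order** is (gated, original) in the block's first half and
  (first-half, upsampled-deep) at the fusion; the orders are
  learnable-equivalent and fixed for reproducibility.
* **Spatial weight normalization.** Softmax over all $H \times W$ positions
  is the default. Over a 256x256 map this yields weights of order $10^{-5}$;
  the residual form $A' + W_P \odot A'$ keeps the block near-identity rather
  than attenuating, and an element-wise logistic is offered as an
  alternative.
* **Channel-attention reduction** defaults to $r = 16$ (the standard
  squeeze-excite ratio); fused channel counts must be divisible by $r$, so
  narrow models pass a smaller ratio.
* **Batch normalization** uses batch statistics (momentum 0.1 running
  moments) in training and the running moments in evaluation; after very
  short runs the running moments are still warming up, which only affects
  smoke-scale experiments.
* **Bilinear resizing** uses half-pixel centers; mask resizing in the data
  loader is nearest-neighbour to preserve binarity, and masks binarize at
  intensity 128/255.
* **Degenerate inputs.** Pooling kernels larger than the feature map are
  clamped to it (relevant at 64x64 inputs, where the bottleneck grid is
  2x2); confusion-count metrics return `NA` on empty denominators; the Dice
  loss defines the all-empty case via its smoothing constant.

## Scaled-down study sizes

The bundled acceptance study and tests run the full pipeline at sizes chosen
for a single CPU: 64x64 images, base width 16 (reduction 16), 200 training /
30 validation / 50 test images at contrast 0.5, batch 12, learning rate
$10^{-3}$, at most 30 epochs with early stop once validation Jaccard reaches
0.85. The raised learning rate and narrow width are the scaled-study
counterparts of the full-size recipe; at this scale the full FAC-Net reaches
a test Jaccard well above 0.75 within a handful of epochs. The ablation
harness runs the four module combinations (backbone, +FFB, +AMB, both) and
the five spatial-statistic sets (mode, mode+avg, mode+max, max+avg,
mode+max+avg) under identical seeds and splits; at smoke scale its rows are
not expected to reproduce full-scale rankings, only to demonstrate the
harness and seed discipline.

## Known limitations

* CPU-only and single-threaded linear algebra: full-size (256x256, width
  64, 200-epoch) training is out of reach here; the package targets
  correctness and desk-scale experiments.
* The quantized channel mode blocks gradient flow through its branch by
  construction; architectures that rely on gradients through that statistic
  would need a soft relaxation.
* Published shapes print the spatial weight map as a per-channel vector;
  a per-position map is the only reading consistent with a spatial
  attention built from per-position statistics, and is what is implemented.
* The encoder-stage geometry (stages at $H/4 \dots H/32$ behind a stride-2
  stem) follows the CE-Net/ResNet convention and the documented stage
  shapes; descriptions that halve from full resolution would shift all
  stages by one octave.
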