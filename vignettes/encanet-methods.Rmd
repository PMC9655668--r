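---
title: "ENCANet: attention-based blood-cell detection and exact complexity audits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ENCANet: attention-based blood-cell detection and exact complexity audits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encanet)
```

## The problem and the model

Automated counting and localization of blood cells in smear microscopy asks
for a detector that is accurate on three very different object classes --
many medium-sized red blood cells (RBC), a few large white blood cells
(WBC), and tiny platelets -- while staying small enough to deploy near the
microscope. ENCANet is a single-level anchor-based detector built from three
components:

* **Backbone** -- an EfficientNet feature extractor (B0 by default, B1--B3
  supported), consuming `N x 416 x 416 x 3` images and emitting a single
  stride-32 feature map (`13 x 13` cells at 416).
* **Encoder** -- a 1x1 convolution (with bias) plus batch norm projects the
  backbone channels to 512, and a pluggable attention block refines the map.
  The block can be squeeze-and-excitation (SE), efficient channel attention
  (ECA), the channel-attention module of CBAM (CAM), the enhanced channel
  attention module (ECAM), pure spatial attention (SAM), or the sequential
  channel-then-spatial combinations CBAM and ECBAM. The encoder preserves
  the `N x 512 x H x W` contract. A dilated residual encoder (a 3x3
  convolution plus four bottlenecks at dilations 2, 4, 6, 8) is implemented
  for complexity comparisons: removing it saves 3.48 M parameters, which is
  the design observation the attention encoders exploit.
* **Decoder** -- two parallel heads of depthwise-separable modules (2 for
  classification, 4 for regression; each module is a 3x3 depthwise + 1x1
  pointwise convolution with batch norms, ReLU and a residual connection),
  finished by 3x3 predictors for K class scores, 4 box deltas and an
  objectness logit per anchor (A = 5 square anchors of side 32--512 per
  cell). The ranking score of an (anchor, class) pair is
  `sigmoid(class) * sigmoid(objectness)`.

### The attention operators

With a feature map $X \in \mathbb{R}^{C\times H\times W}$, the channel
descriptors are the global average pool
$z_c = \tfrac{1}{HW}\sum_{i,j} x_c(i,j)$ and the global max pool
$m_c = \max_{i,j} x_c(i,j)$. SE excites the averaged descriptor through a
bottleneck MLP, $P_C = \sigma(W_2\,\delta(W_1 z + b_1) + b_2)$ with
reduction ratio $r$ (default 16, so $W_1 \in \mathbb{R}^{C/r \times C}$);
CAM evaluates the *same* MLP on both pooled descriptors and sums before the
sigmoid. ECAM instead gates the average-pooled descriptor by the sigmoid of
the max-pooled one, $z'_c = \sigma(m_c)\, z_c$, and excites only once:
$P_C = \sigma(W_2\,\delta(W_1 z'))$ -- one MLP evaluation per forward pass
where CAM needs two. Setting the gate to 1 reduces ECAM exactly to SE, a
property the test suite asserts bitwise. Spatial attention stacks the
channel-wise mean and max maps, convolves them with a single `k x k` filter
(default k = 7, with bias, zero padding `(k-1)/2`) and applies a sigmoid;
ECBAM is ECAM followed by spatial attention, CBAM is CAM followed by the
same. Every gate lies strictly in (0, 1).

All operators exist twice in the package, deliberately: as transparent pure-R
functions (`global_average_pool()`, `ecam_attention()`, ...) and as
instruction tapes executed by the compiled engine that trains the full
network. The test suite cross-checks the two routes against each other and
against naive scalar loop oracles.

## Exact parameter audits

`audit_params()` builds a configuration's instruction tape and sums the
shapes of every trainable array (batch-norm affine pairs count; running
statistics do not). This reproduces the familiar complexity-table figures
at two-decimal millions rounding (half-up): 6.46 M for the encoder-free B0
baseline, 8.97 / 10.22 / 13.28 M for B1/B2/B3, 6.49 M with ECAM, 6.5 M with
ECBAM, 6.72 / 6.59 / 6.53 / 6.48 M across reduction ratios 2--32, 6.49 M at
spatial kernel 3, and the 3,484,160-parameter dilated encoder.

Two reconstruction choices deserve a note, because the source architecture
is only partially specified in prose:

* **The projection convolution carries a bias.** With the bias (512
  parameters), B0+ECBAM totals 6,495,015 and rounds to 6.50 -> "6.5 M",
  while the kernel-3/5 variants stay at 6.49 M and every other printed total
  is matched simultaneously; without it, B0+ECBAM rounds to 6.49 M and the
  published table cannot be reproduced. The bias convention is therefore
  fixed by the tables themselves.
* **The excitation MLPs carry biases** (`b1`, `b2`), for the same reason:
  only the with-bias convention reproduces the +ECAM totals.

The decoder internals (2 + 4 depthwise-separable modules, biased
predictors, A = 5) are reconstructed from the base detector family this
architecture inherits; the reconstruction is validated by exact agreement
with six independent printed totals and then frozen.

`attention_param_count()` gives the closed-form module costs: 33,312
parameters for ECAM at C = 512, r = 16; 99 for the 7x7 spatial stage;
33,411 (0.033 M) for ECBAM -- under 0.04 M for the whole encoder.

## The compute engine

No CNN autograd library is part of the package's dependency footprint, so
the forward/backward engine is implemented in C++ (RcppArmadillo): im2col +
GEMM convolutions (1x1 convolutions collapse to a single GEMM per image),
direct depthwise convolutions, batch normalization in training and inference
modes, SiLU/ReLU/sigmoid, global and channel-wise poolings, broadcast gating
and residual addition. The engine is templated on precision: the double path
backs finite-difference gradient checks in the tests; the float path, with a
vectorizable polynomial `exp` and AVX2 function multi-versioning on the hot
elementwise kernels, carries training. Parameters, momentum buffers and
gradients stay resident in the engine between iterations; R computes only
the detection loss and its gradient with respect to the three small head
maps.

## Training machinery

* **Matching.** Uniform matching: each ground-truth box takes its k = 4
  nearest anchors by center distance (ties between co-centered anchors of
  different sizes resolve toward the best size match); unmatched anchors
  with IoU > 0.7 to any box are ignored, and positives with IoU < 0.15 to
  their own box are demoted to ignored.
* **Losses.** Focal classification loss (alpha 0.25, gamma 2) on
  `sigmoid(class) * sigmoid(objectness)` over non-ignored anchors,
  normalized by the number of positives; box regression on positives
  combines the GIoU loss with a delta-space smooth-L1 (Huber) term toward
  the encoded targets. The Huber term is a conditioning choice: with pure
  GIoU and randomly initialized features, offset anchors first inflate
  ("grow to cover") and then stall in a regime where the GIoU gradient is
  vanishingly small; the Huber term keeps a well-scaled pull toward the
  target throughout and damps to zero at the solution.
* **Box coder.** Standard center/size deltas with log-scaled sizes. The
  decode saturates smoothly (identity up to |delta| = 2, tanh approach to
  the cap beyond, cap log(1000/16) for sizes) instead of clamping hard; a
  hard clamp zeroes the gradient once a delta overshoots and permanently
  traps it, which we observed within ten iterations at detector learning
  rates.
* **Optimizer.** SGD with momentum 0.9, weight decay 1e-4 on convolution
  weights, global gradient-norm clipping at 10, and the published schedule:
  mini-batch 4, base learning rate 0.12 reached after 1500 linear warmup
  iterations (start factor 1/1000), 12 epochs, no decay steps (none are
  published; constant-after-warmup is declared). Momentum, weight decay,
  clipping and the warmup start factor are not published either; they are
  conventional values, declared in `train_config()` and overridable.
* **Initialization.** Kaiming (fan-out) normal convolutions, unit/zero batch
  norms, and the focal prior `-log((1-0.01)/0.01)` on the classification and
  class-prior biases so the first iterations are not dominated by the
  negative sea.
* **Augmentation.** Horizontal and vertical flips, each with probability
  0.5, training only; anisotropic resize to the square training size.

### A note on short-run stability

The effective per-output step of SGD on a predictor scales like
`lr * ||features||^2 / (n_pos * (1 - momentum))`. At the published settings
this is balanced by large effective batches and long schedules; in the
short smoke runs this package uses for end-to-end validation (see below),
the same settings put the regression head in an oscillatory regime. The
smoke runs therefore use a run-length-appropriate setting -- learning rate
0.0015 with momentum 0.9 (or equivalently ~0.005 with momentum 0) and a
50-iteration warmup -- chosen from this step-size analysis. The published full-scale recipe
remains the package default.

## Synthetic blood smears

`generate_scene()` renders soft-edged rotated ellipses on a pale background:
10--40 RBC-like cells of radius 14--26 px (pale red), 1--3 WBC-like cells of
radius 28--44 px drawn as a violet nucleus on lighter cytoplasm, and 2--8
platelet-like specks of radius 4--9 px, at 416 x 416 with per-object color
jitter, a same-class bounding-box IoU cap of 0.3 enforced by rejection
sampling (100 attempts, then the object is dropped with a warning), and
additive Gaussian noise (sd 0.02). Boxes are tight extents of the rotated
ellipses. Scenes are bit-reproducible given (config, seed), and per-scene
seeds are `master seed + index` so datasets extend without reshuffling.

What this emulates is the *class structure* of blood-smear data -- the
frequency ordering (RBC > platelets > WBC) and the size ordering
(WBC > RBC > platelets) -- not its photometric statistics: there is no
stain variation, no focus blur, no cell clumping or occlusion texture.
Passing the pipeline tests on this generator shows the implementation
learns and evaluates correctly end to end; it says nothing quantitative
about accuracy on real smears.

## Evaluation

`coco_eval()` implements the standard COCO protocol: IoU thresholds 0.5 to
0.95 in steps of 0.05, 101-point interpolated precision, area splits at
32^2 and 96^2 pixels, at most 100 detections per image, categories without
ground truth excluded from means, values on the 0--100 scale. The test
suite checks it against an independent numpy implementation of the same
protocol to 1e-4. Inference applies a 0.05 score floor and per-class greedy
NMS at IoU 0.6.

`attention_map()` reproduces the qualitative attention-visualization
protocol: the channel mean of the feature map tapped after the backbone or
after the encoder, min-max normalized (a constant map normalizes to zero),
bilinearly upsampled to the image and blended over it.

## Problem sizes used by the checks

The packaged validation runs are sized for a single CPU:

* attention-operator oracles: 100 random `4 x 8 x 5 x 5` maps per operator;
* parameter audits: every backbone and encoder variant, exact integers;
* end-to-end smoke: ENCANet-B0 (ECBAM) trained 300 iterations on 40
  synthetic scenes at input size 224 and scored on 10 held-out scenes (the
  suite runs one seed of this);
* loss-decrease property: 200 iterations on a fixed 8-image batch of 64 px
  scenes drawn with proportionally scaled-down cell geometry, ten seeds.

Two structural facts bound what the 224-px smoke run can show. First, the
platelet class falls entirely below the matcher's demotion floor (a 4--10 px
box against a 32 px anchor has IoU < 0.15 at input 224), so platelets are
never trained at that scale and the class-averaged AP50 is capped near 67
even with perfect RBC/WBC detection. Second, and more fundamentally, with a
randomly initialized backbone the stride-32 features carry no sub-cell
position information early in training: replacing every predicted box by
its raw anchor and scoring with an oracle yields AP50 = 8.6 at input 224,
so a high AP50 requires a converged regression head, and across every
stable optimizer setting we scanned the delta-space regression error
plateaus around 0.3 within the smoke budget (a 5x-longer diagnostic run
shows a flat AP50 trend). The loss-decrease property is robust -- total
loss falls by an order of magnitude in every seed -- but the suite's
AP50 > 50 assertion on the 300-iteration run documents an aspiration this
from-scratch configuration does not reach, not a verified property; with a
pretrained backbone (user-suppliable) or a much longer schedule the same
pipeline is expected to close that gap.

## Known limitations

* The backbone is randomly initialized by default; reproducing published
  accuracy on real data would require pretrained weights and GPU-scale
  training, which are out of scope.
* GFLOP counting is not implemented: the printed computational-cost figures
  in the source tables follow a convention no standard FLOP count
  reproduces at stride 32, so only parameter counts are audited.
* The GIoU gradient is obtained by well-conditioned central differences on
  the decoded box rather than a closed form; the difference is well below
  optimizer noise, and the end-to-end gradient path is verified against
  finite differences in the tests.
* Training throughput is of order one second per batch-4 iteration at input
  224 on one CPU core -- adequate for the packaged validations, not for
  full-schedule training on real datasets.
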