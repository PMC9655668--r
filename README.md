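# encanet

Attention-based blood-cell detection with exact model-complexity audits, in R.

Microscopy blood smears contain three object classes a clinical pipeline
needs localized and counted: red blood cells (RBC, many, medium), white
blood cells (WBC, few, large) and platelets (few, tiny). `encanet`
implements ENCANet, a single-level anchor-based detector for this task:

* an **EfficientNet-B0..B3 backbone** (stride-32 feature extractor),
* an **attention encoder** — a 1×1 projection to 512 channels followed by a
  pluggable attention block: SE, ECA, CAM, the Enhanced Channel Attention
  Module (ECAM), spatial attention, CBAM, or ECBAM (= ECAM + spatial
  attention). ECAM gates the average-pooled channel descriptor by the
  sigmoid of the max-pooled one, `z'_c = σ(m_c)·z_c`, then excites it once
  through a bottleneck MLP, `P_C = σ(W₂ δ(W₁ z'))` — one MLP evaluation
  where CBAM's channel stage needs two,
* a **dual-head depthwise-separable decoder** (2 classification + 4
  regression modules, K·A class scores, 4A box deltas and A objectness
  logits per 13×13 cell at input 416, A = 5 anchors of side 32–512).

Every attention operator also exists as a transparent pure-R function, and
the package ships an **exact trainable-parameter audit** that reproduces the
published complexity tables (6.46 M encoder-free B0 baseline, 6.49 M with
ECAM, 6.5 M with ECBAM, 8.97/10.22/13.28 M for B1–B3, the 3.48 M dilated
encoder, the reduction-ratio and kernel-size sweeps), a synthetic
blood-smear generator with COCO annotations, COCO dataset IO with the 7:2:1
split protocol, SGD training (focal + GIoU losses, uniform anchor matching,
linear warmup) on a hand-written RcppArmadillo forward/backward engine,
MS-COCO evaluation metrics, and attention-map visualization.

## Worked example

```r
library(encanet)

# exact complexity audit of ENCANet-B0 with the ECBAM encoder
audit_params(detector_config("b0", "ecbam"))
#> Trainable parameters
#>   backbone      4007548
#>   projection     656896
#>   encoder         33411
#>   decoder       1797160
#>   total         6495015  (6.5 M)

# the ECBAM module itself costs 33,411 parameters (0.033 M)
attention_param_count(attention_config("ecbam"))
#> [1] 33411

# the attention math, on a toy feature map
set.seed(1)
x <- array(rnorm(1 * 8 * 5 * 5), c(1, 8, 5, 5))
w <- mlp_weights(C = 8, r = 2)
range(ecam_attention(x, w))       # per-channel gates, strictly inside (0, 1)
#> [1] 0.4995 0.5003

# synthetic blood smears with COCO annotations, and a short training run
train <- generate_dataset(scene_config(), n_images = 40, seed = 100)
model <- encanet(detector_config("b0", "ecbam"), seed = 1)
fit <- train_encanet(model, train,
                     train_config(base_lr = 0.0015, warmup_iters = 50,
                                  iterations = 300, image_size = 224,
                                  box_weight = 0.1))
test <- generate_dataset(scene_config(), n_images = 10, seed = 900)
evaluate_encanet(fit$model, test, eval_size = 224)$metrics
```

The audit block prints the component-wise parameter counts shown above —
the backbone is the EfficientNet-B0 feature extractor (4,007,548), the
projection is the biased 1×1 conv + batch norm (656,896), ECBAM adds 33,411
(its 33,312-parameter excitation MLP plus the 99-parameter 7×7 spatial
stage), and the dual-head decoder contributes 1,797,160; the total rounds
to the conventional 6.5 M figure. The training block runs the end-to-end
smoke workout used by the test suite; the evaluation returns the COCO
metrics (AP, AP50, AP75 and the area-stratified variants) on held-out
synthetic scenes.

A thin command-line front end is installed with the package
(`system.file("cli", "encanet", package = "encanet")`) with subcommands
`generate`, `audit`, `train`, `eval` and `visualize`.

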