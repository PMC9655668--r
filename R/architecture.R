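# Full detector assembly: backbone -> 1x1 projection to 512 channels ->
# encoder (attention variant, none, or the dilated encoder kept for
# comparison audits) -> dual-head depthwise-separable decoder. Also the
# exact parameter-audit facility.

#' Detector configuration
#'
#' @param backbone one of `"b0"`, `"b1"`, `"b2"`, `"b3"` (EfficientNet
#'   variants).
#' @param encoder an [attention_config()], or the strings `"none"` (bare 1x1
#'   projection baseline), `"dilated"` (the dilated residual encoder, kept for
#'   complexity comparisons), or an attention kind name such as `"ecbam"`
#'   which is expanded with default settings.
#' @param num_classes number of object categories K (default 3: Platelets,
#'   RBC, WBC).
#' @param anchors_per_cell anchors A per feature-map cell (default 5).
#' @param image_size input image side (default 416); must be divisible by
#'   `stride`.
#' @param stride backbone output stride (32).
#' @return object of class `detector_config`.
#' @export
detector_config <- function(backbone = "b0", encoder = "ecbam",
                            num_classes = 3, anchors_per_cell = 5,
                            image_size = 416, stride = 32) {
  effnet_multipliers(backbone)  # validates
  if (is.character(encoder)) {
    encoder <- if (encoder %in% c("none", "dilated")) encoder
               else attention_config(encoder)
  } else if (!inherits(encoder, "attention_config"))
    stop("encoder must be an attention_config or 'none'/'dilated'")
  if (image_size %% stride != 0) stop("image_size must be divisible by stride")
  structure(list(backbone = backbone, encoder = encoder,
                 num_classes = as.integer(num_classes),
                 anchors_per_cell = as.integer(anchors_per_cell),
                 projection_channels = 512L,
                 image_size = as.integer(image_size),
                 stride = as.integer(stride)),
            class = "detector_config")
}

encoder_kind <- function(cfg) {
  if (is.character(cfg$encoder)) cfg$encoder else cfg$encoder$kind
}

# 1x1 projection conv (with bias) + BN, backbone channels -> 512
build_projection <- function(nb, x, c_in) {
  v <- nb_conv(nb, x, c_in, 512, 1, bias = TRUE, name = "projection.conv",
               group = "projection")
  nb_bn(nb, v, 512, "projection.bn", "projection", eps = 1e-5)
}

# attention encoder instructions on a 512-channel map; returns output id
build_attention_encoder <- function(nb, x, acfg) {
  C <- acfg$channels; r <- acfg$reduction; g <- "encoder"
  mlp_gate <- function(d) {
    d <- nb_conv(nb, d, C, C %/% r, 1, bias = acfg$mlp_bias,
                 name = "encoder.mlp.fc1", group = g)
    d <- nb_act(nb, d, "relu")
    nb_conv(nb, d, C %/% r, C, 1, bias = acfg$mlp_bias,
            name = "encoder.mlp.fc2", group = g)
  }
  mlp_pids <- function() {
    nms <- vapply(nb$params, `[[`, "", "name")
    list(fc1 = which(nms %in% c("encoder.mlp.fc1.w", "encoder.mlp.fc1.b")),
         fc2 = which(nms %in% c("encoder.mlp.fc2.w", "encoder.mlp.fc2.b")))
  }
  channel_stage <- function(x, kind) {
    switch(kind,
      se = {
        d <- mlp_gate(nb_gap(nb, x))
        nb_mul(nb, x, nb_act(nb, d, "sigmoid"))
      },
      cam = {
        a <- mlp_gate(nb_gap(nb, x))
        ids <- mlp_pids()
        b <- nb_conv_shared(nb, nb_gmp(nb, x), ids$fc1)
        b <- nb_act(nb, b, "relu")
        b <- nb_conv_shared(nb, b, ids$fc2)
        nb_mul(nb, x, nb_act(nb, nb_add(nb, a, b), "sigmoid"))
      },
      ecam = {
        z <- nb_gap(nb, x)
        gate <- nb_act(nb, nb_gmp(nb, x), "sigmoid")
        nb_mul(nb, x, nb_act(nb, mlp_gate(nb_mul(nb, z, gate)), "sigmoid"))
      },
      eca = {
        d <- nb_conv1dch(nb, nb_gap(nb, x), eca_kernel_size(C),
                         name = "encoder.eca", group = g)
        nb_mul(nb, x, nb_act(nb, d, "sigmoid"))
      },
      stop("bad channel stage"))
  }
  spatial_stage <- function(t) {
    k <- acfg$spatial_kernel
    s <- nb_chstat(nb, t)
    s <- nb_conv(nb, s, 2, 1, k, pad = (k - 1) / 2, bias = TRUE,
                 name = "encoder.sam.conv", group = g)
    nb_mul(nb, t, nb_act(nb, s, "sigmoid"))
  }
  switch(acfg$kind,
         none = x,
         se = channel_stage(x, "se"),
         eca = channel_stage(x, "eca"),
         cam = channel_stage(x, "cam"),
         ecam = channel_stage(x, "ecam"),
         sam = spatial_stage(x),
         cbam = spatial_stage(channel_stage(x, "cam")),
         ecbam = spatial_stage(channel_stage(x, "ecam")))
}

# dilated residual encoder (comparison/audit): 3x3 conv + BN, then four
# residual bottlenecks with dilations 2, 4, 6, 8
build_dilated_encoder <- function(nb, x) {
  g <- "encoder"
  v <- nb_conv(nb, x, 512, 512, 3, pad = 1, bias = TRUE,
               name = "encoder.pre.conv", group = g)
  v <- nb_bn(nb, v, 512, "encoder.pre.bn", g, eps = 1e-5)
  for (i in seq_along(c(2, 4, 6, 8))) {
    d <- c(2, 4, 6, 8)[i]
    nm <- sprintf("encoder.block%d", i)
    inp <- v
    v <- nb_conv(nb, v, 512, 128, 1, bias = TRUE, name = paste0(nm, ".reduce"),
                 group = g)
    v <- nb_bn(nb, v, 128, paste0(nm, ".reduce.bn"), g, eps = 1e-5)
    v <- nb_act(nb, v, "relu")
    v <- nb_conv(nb, v, 128, 128, 3, pad = d, dilation = d, bias = TRUE,
                 name = paste0(nm, ".dilated"), group = g)
    v <- nb_bn(nb, v, 128, paste0(nm, ".dilated.bn"), g, eps = 1e-5)
    v <- nb_act(nb, v, "relu")
    v <- nb_conv(nb, v, 128, 512, 1, bias = TRUE, name = paste0(nm, ".expand"),
                 group = g)
    v <- nb_bn(nb, v, 512, paste0(nm, ".expand.bn"), g, eps = 1e-5)
    v <- nb_act(nb, v, "relu")
    v <- nb_add(nb, v, inp)
  }
  v
}

# one depthwise-separable decoder module with residual connection
build_dw_module <- function(nb, x, name) {
  g <- "decoder"
  v <- nb_dwconv(nb, x, 512, 3, pad = 1, name = paste0(name, ".dw"), group = g)
  v <- nb_bn(nb, v, 512, paste0(name, ".dw.bn"), g, eps = 1e-5)
  v <- nb_conv(nb, v, 512, 512, 1, name = paste0(name, ".pw"), group = g)
  v <- nb_bn(nb, v, 512, paste0(name, ".pw.bn"), g, eps = 1e-5)
  v <- nb_act(nb, v, "relu")
  nb_add(nb, v, x)
}

# dual-head decoder: 2 cls + 4 reg DW modules, then 3x3 predictors (bias).
# Classification bias starts at the focal prior so early training is stable.
build_decoder <- function(nb, x, K, A) {
  g <- "decoder"
  prior <- -log((1 - 0.01) / 0.01)
  cls <- x
  for (i in 1:2) cls <- build_dw_module(nb, cls, sprintf("decoder.cls%d", i))
  reg <- x
  for (i in 1:4) reg <- build_dw_module(nb, reg, sprintf("decoder.reg%d", i))
  cls_out <- nb_conv(nb, cls, 512, K * A, 3, pad = 1, bias = TRUE,
                     name = "decoder.pred.cls", group = g,
                     init = list(kind = "normal", sd = 0.01),
                     bias_init = prior)
  box_out <- nb_conv(nb, reg, 512, 4 * A, 3, pad = 1, bias = TRUE,
                     name = "decoder.pred.box", group = g,
                     init = list(kind = "const", val = 0))
  obj_out <- nb_conv(nb, reg, 512, A, 3, pad = 1, bias = TRUE,
                     name = "decoder.pred.obj", group = g,
                     init = list(kind = "normal", sd = 0.01))
  list(cls = cls_out, box = box_out, obj = obj_out)
}

build_detector_net <- function(cfg) {
  nb <- new_net()
  bb <- build_backbone(nb, 1L, cfg$backbone)
  nb_tap(nb, "after_backbone", bb$out)
  v <- build_projection(nb, bb$out, bb$channels)
  kind <- encoder_kind(cfg)
  v <- if (kind == "none") v
       else if (kind == "dilated") build_dilated_encoder(nb, v)
       else build_attention_encoder(nb, v, cfg$encoder)
  nb_tap(nb, "after_encoder", v)
  heads <- build_decoder(nb, v, cfg$num_classes, cfg$anchors_per_cell)
  nb_finish(nb, outputs = heads)
}

#' Build an ENCANet detector
#'
#' Assembles the full detector (backbone, 1x1 projection to 512 channels,
#' encoder, dual-head decoder) and initializes its weights.
#'
#' @param config a [detector_config()]; individual fields can also be passed
#'   through `...` for convenience, e.g. `encanet(backbone = "b0", encoder =
#'   "ecbam")`.
#' @param seed RNG seed for weight initialization.
#' @param ... fields forwarded to [detector_config()] when `config` is
#'   missing.
#' @return object of class `encanet`: the configuration, the instruction
#'   tape, the weight list and the batch-norm state.
#' @export
encanet <- function(config = NULL, seed = 1L, ...) {
  if (is.null(config)) config <- detector_config(...)
  net <- build_detector_net(config)
  structure(list(config = config, net = net,
                 params = init_net_params(net, seed),
                 state = init_net_state(net)),
            class = "encanet")
}

#' Forward pass of a detector
#'
#' Runs images through the network and returns the raw head outputs
#' (classification, box-delta and objectness maps), optionally intermediate
#' taps.
#'
#' @param model an [encanet()] model.
#' @param x numeric array `(N, 3, S, S)` of normalized images.
#' @param training logical; use batch statistics and record an autodiff cache.
#' @param taps optional character vector of tap names (`"after_backbone"`,
#'   `"after_encoder"`) to return instead of the heads.
#' @param keep_cache keep the autodiff cache for a backward pass.
#' @param precision `"float"` (default) or `"double"`.
#' @return list with `values` (named arrays), updated `state`, and `cache`
#'   when requested.
#' @export
encanet_forward <- function(model, x, training = FALSE, taps = NULL,
                            keep_cache = FALSE, precision = "float") {
  outs <- model$net$outputs
  if (!is.null(taps)) {
    bad <- setdiff(taps, names(model$net$taps))
    if (length(bad)) stop("unknown tap point '", bad[1], "'")
    outs <- model$net$taps[taps]
  }
  net_forward(model$net, model$params, model$state, x, training = training,
              outputs = outs, keep_cache = keep_cache, precision = precision)
}

#' Exact trainable-parameter audit
#'
#' Enumerates every trainable array of a detector configuration (batch-norm
#' affine vectors included; running statistics excluded) and reports
#' per-component and total counts plus the conventional "millions to two
#' decimals" figure used in model-complexity tables.
#'
#' @param cfg a [detector_config()] (or an `encanet` model).
#' @return object of class `param_audit` with fields `backbone_params`,
#'   `projection_params`, `encoder_params`, `decoder_params`, `total`,
#'   `total_millions_2dp`.
#' @export
audit_params <- function(cfg) {
  if (inherits(cfg, "encanet")) cfg <- cfg$config
  net <- build_detector_net(cfg)
  counts <- vapply(net$params, function(p) prod(p$shape), 0)
  groups <- vapply(net$params, `[[`, "", "group")
  tot <- function(g) as.integer(sum(counts[groups == g]))
  total <- as.integer(sum(counts))
  structure(list(backbone_params = tot("backbone"),
                 projection_params = tot("projection"),
                 encoder_params = tot("encoder"),
                 decoder_params = tot("decoder"),
                 total = total,
                 total_millions_2dp = round_half_up(total / 1e6, 2)),
            class = "param_audit")
}

#' @export
print.param_audit <- function(x, ...) {
  cat("Trainable parameters\n")
  cat(sprintf("  backbone   %10d\n", x$backbone_params))
  cat(sprintf("  projection %10d\n", x$projection_params))
  cat(sprintf("  encoder    %10d\n", x$encoder_params))
  cat(sprintf("  decoder    %10d\n", x$decoder_params))
  cat(sprintf("  total      %10d  (%.4g M)\n", x$total, x$total_millions_2dp))
  invisible(x)
}

#' @export
print.encanet <- function(x, ...) {
  k <- encoder_kind(x$config)
  cat(sprintf("ENCANet detector: backbone %s, encoder %s, K=%d classes, A=%d anchors\n",
              x$config$backbone, k, x$config$num_classes,
              x$config$anchors_per_cell))
  if (inherits(x$config$encoder, "attention_config") &&
      k %in% c("se", "cam", "ecam", "cbam", "ecbam"))
    cat(sprintf("  reduction r=%d, spatial kernel k=%d\n",
                x$config$encoder$reduction, x$config$encoder$spatial_kernel))
  print(audit_params(x$config))
  invisible(x)
}

#' @export
summary.encanet <- function(object, ...) {
  print(object)
  cat(sprintf("  input %dx%dx3, stride %d, grid %dx%d\n",
              object$config$image_size, object$config$image_size,
              object$config$stride,
              object$config$image_size %/% object$config$stride,
              object$config$image_size %/% object$config$stride))
  invisible(object)
}

#' Save / load a detector checkpoint
#'
#' Single-file archive (RDS) of the model object: configuration, weights and
#' batch-norm state.
#'
#' @param model an `encanet` model.
#' @param path file path.
#' @return `load_encanet` returns the model.
#' @export
save_encanet <- function(model, path) {
  stopifnot(inherits(model, "encanet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_encanet
#' @export
load_encanet <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "encanet")) stop("not an encanet checkpoint")
  m
}
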