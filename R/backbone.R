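# EfficientNet-B0..B3 feature extractors, reconstructed from the published
# compound-scaling recipe (stem -> seven MBConv stages -> 1x1 expansion head,
# classifier removed). Channel widths round to multiples of 8 with the
# standard divisibility rule; depths scale by ceiling. Squeeze-excitation
# inside each MBConv squeezes to (block input channels)/4 with biased 1x1
# convs. The resulting trainable-parameter counts match the reference
# implementation exactly (4,007,548 for B0 through 10,696,232 for B3).

effnet_multipliers <- function(variant) {
  switch(variant,
         b0 = c(width = 1.0, depth = 1.0),
         b1 = c(width = 1.0, depth = 1.1),
         b2 = c(width = 1.1, depth = 1.2),
         b3 = c(width = 1.2, depth = 1.4),
         stop("unknown backbone variant '", variant, "'"))
}

make_divisible <- function(v, divisor = 8) {
  new_v <- max(divisor, (as.integer(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

# stage table: expansion, base output channels, base repeats, kernel, stride
effnet_base_stages <- function() {
  list(c(1, 16, 1, 3, 1), c(6, 24, 2, 3, 2), c(6, 40, 2, 5, 2),
       c(6, 80, 3, 3, 2), c(6, 112, 3, 5, 1), c(6, 192, 4, 5, 2),
       c(6, 320, 1, 3, 1))
}

#' Backbone output channel width
#'
#' Channel count of the stride-32 feature map each EfficientNet variant
#' emits (1280 for B0/B1, 1408 for B2, 1536 for B3).
#'
#' @param variant one of `"b0"`, `"b1"`, `"b2"`, `"b3"`.
#' @return integer channel count.
#' @export
backbone_channels <- function(variant) {
  m <- effnet_multipliers(variant)
  make_divisible(1280 * m["width"])
}

# emit backbone instructions; returns list(out = value id, channels)
build_backbone <- function(nb, x, variant) {
  m <- effnet_multipliers(variant)
  rf <- function(ch) make_divisible(ch * m["width"])
  rd <- function(n) as.integer(ceiling(m["depth"] * n))
  g <- "backbone"
  stem <- rf(32)
  v <- nb_conv(nb, x, 3, stem, 3, stride = 2, pad = 1,
               name = "backbone.stem.conv", group = g)
  v <- nb_bn(nb, v, stem, "backbone.stem.bn", g)
  v <- nb_act(nb, v, "silu")
  cin <- stem
  si <- 0
  for (st in effnet_base_stages()) {
    si <- si + 1
    e <- st[1]; cout <- rf(st[2]); reps <- rd(st[3]); k <- st[4]; s0 <- st[5]
    for (b in seq_len(reps)) {
      ci <- if (b == 1) cin else cout
      s <- if (b == 1) s0 else 1
      nm <- sprintf("backbone.s%d.b%d", si, b)
      cexp <- ci * e
      inp <- v
      if (e != 1) {
        v <- nb_conv(nb, v, ci, cexp, 1, name = paste0(nm, ".expand.conv"),
                     group = g)
        v <- nb_bn(nb, v, cexp, paste0(nm, ".expand.bn"), g)
        v <- nb_act(nb, v, "silu")
      }
      v <- nb_dwconv(nb, v, cexp, k, stride = s, pad = (k - 1) / 2,
                     name = paste0(nm, ".dw"), group = g)
      v <- nb_bn(nb, v, cexp, paste0(nm, ".dw.bn"), g)
      v <- nb_act(nb, v, "silu")
      # squeeze-excitation: squeeze to block-input channels / 4, biased convs
      sq <- max(1L, ci %/% 4L)
      d <- nb_gap(nb, v)
      d <- nb_conv(nb, d, cexp, sq, 1, bias = TRUE,
                   name = paste0(nm, ".se.fc1"), group = g)
      d <- nb_act(nb, d, "silu")
      d <- nb_conv(nb, d, sq, cexp, 1, bias = TRUE,
                   name = paste0(nm, ".se.fc2"), group = g)
      d <- nb_act(nb, d, "sigmoid")
      v <- nb_mul(nb, v, d)
      v <- nb_conv(nb, v, cexp, cout, 1, name = paste0(nm, ".project.conv"),
                   group = g)
      v <- nb_bn(nb, v, cout, paste0(nm, ".project.bn"), g)
      if (s == 1 && ci == cout) v <- nb_add(nb, v, inp)
    }
    cin <- cout
  }
  head <- rf(1280)
  v <- nb_conv(nb, v, cin, head, 1, name = "backbone.head.conv", group = g)
  v <- nb_bn(nb, v, head, "backbone.head.bn", g)
  v <- nb_act(nb, v, "silu")
  list(out = v, channels = head)
}
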