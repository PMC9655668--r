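# Pure-R reference implementations of the channel / spatial attention
# operators. These are the mathematically transparent forms used for testing
# and exploration; the C++ engine builds the same operators as network
# instructions for training (and the two routes are cross-checked in the test
# suite).
#
# Conventions: a FeatureMap is a 4-D numeric array (N, C, H, W); a channel
# descriptor is an (N, C) matrix; channel attention is an (N, C) matrix of
# gates in (0,1); spatial attention is an (N, 1, H, W) array of gates.

check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("feature map must be a 4-D array (N, C, H, W)")
  d <- dim(x)
  if (any(d < 1L)) stop("degenerate feature map: all dimensions must be >= 1")
  if (d[3] * d[4] == 0L) stop("degenerate feature map: empty spatial extent")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(d)
}

#' Global average pooling (squeeze step)
#'
#' Squeezes the spatial extent of every channel into a scalar descriptor,
#' \eqn{z_c = \frac{1}{HW}\sum_{i,j} x_c(i,j)}, per batch element. This is the
#' squeeze step of the SE block.
#'
#' @param x feature map, 4-D array `(N, C, H, W)`, finite.
#' @return channel descriptor matrix `(N, C)`.
#' @export
global_average_pool <- function(x) {
  d <- check_feature_map(x)
  matrix(rowMeans(matrix(x, d[1] * d[2])), d[1], d[2])
}

#' Global max pooling
#'
#' Per-channel maximum over the spatial extent,
#' \eqn{m_c = \max_{i,j} x_c(i,j)}, the aggregation CAM adds to the
#' average-pool branch.
#'
#' @inheritParams global_average_pool
#' @return channel descriptor matrix `(N, C)`.
#' @export
global_max_pool <- function(x) {
  d <- check_feature_map(x)
  m <- matrix(x, d[1] * d[2])
  matrix(apply(m, 1L, max), d[1], d[2])
}

#' Excitation MLP weights
#'
#' Container for the two-layer bottleneck MLP shared by SE, CAM and ECAM:
#' \eqn{W_1 \in R^{C/r \times C}}, \eqn{W_2 \in R^{C \times C/r}} with bias
#' vectors. The reduction ratio `r` must divide `C`.
#'
#' @param C channel count.
#' @param r reduction ratio (default 16); must divide `C`.
#' @param W1,b1,W2,b2 optional explicit weights; random N(0, 0.05) weights and
#'   zero biases are drawn when omitted.
#' @param bias logical; keep bias terms (default TRUE).
#' @return object of class `mlp_weights`.
#' @export
mlp_weights <- function(C, r = 16, W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
                        bias = TRUE) {
  if (C %% r != 0) stop("reduction ratio r must divide C")
  Cr <- C %/% r
  if (is.null(W1)) W1 <- matrix(rnorm(Cr * C, sd = 0.05), Cr, C)
  if (is.null(W2)) W2 <- matrix(rnorm(C * Cr, sd = 0.05), C, Cr)
  if (is.null(b1)) b1 <- numeric(Cr)
  if (is.null(b2)) b2 <- numeric(C)
  stopifnot(all(dim(W1) == c(Cr, C)), all(dim(W2) == c(C, Cr)),
            length(b1) == Cr, length(b2) == C)
  if (!bias) { b1[] <- 0; b2[] <- 0 }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, C = C, r = r,
                 bias = bias), class = "mlp_weights")
}

mlp_apply <- function(z, w) {
  # z: (N, C) descriptor -> (N, C) pre-sigmoid logits
  h <- relu(sweep(z %*% t(w$W1), 2, w$b1, `+`))
  sweep(h %*% t(w$W2), 2, w$b2, `+`)
}

#' SE excitation
#'
#' The excitation step of the SE block:
#' \eqn{P_C = \sigma(W_2\,\delta(W_1 z + b_1) + b_2)} with \eqn{\delta} ReLU
#' and \eqn{\sigma} the sigmoid, producing per-channel gates in (0,1).
#'
#' @param z channel descriptor, `(N, C)` matrix or length-`C` vector.
#' @param w [mlp_weights()].
#' @return channel attention matrix `(N, C)`, entries strictly in (0,1).
#' @export
se_excitation <- function(z, w) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (ncol(z) != ncol(w$W1))
    stop("descriptor length ", ncol(z), " does not match MLP input ", ncol(w$W1))
  sigmoid(mlp_apply(z, w))
}

#' CAM channel attention (CBAM channel stage)
#'
#' \eqn{P_C = \sigma(\mathrm{MLP}(\mathrm{AvgPool}(X)) +
#' \mathrm{MLP}(\mathrm{MaxPool}(X)))}; one MLP, shared by both pooled
#' branches, evaluated twice.
#'
#' @inheritParams global_average_pool
#' @param w [mlp_weights()] shared by both branches.
#' @return channel attention matrix `(N, C)`.
#' @export
cam_attention <- function(x, w) {
  z <- global_average_pool(x)
  m <- global_max_pool(x)
  if (ncol(z) != ncol(w$W1))
    stop("channel count ", ncol(z), " does not match MLP input ", ncol(w$W1))
  sigmoid(mlp_apply(z, w) + mlp_apply(m, w))
}

#' ECAM enhanced channel descriptor
#'
#' The enhanced squeeze of ECAM: the max-pooled descriptor acts only through a
#' sigmoid gate on the average-pooled one,
#' \eqn{z'_c = \sigma(m_c)\, z_c}. No MLP touches the max branch, which is how
#' ECAM saves one MLP evaluation relative to CAM.
#'
#' @inheritParams global_average_pool
#' @return enhanced channel descriptor matrix `(N, C)`.
#' @export
ecam_descriptor <- function(x) {
  sigmoid(global_max_pool(x)) * global_average_pool(x)
}

#' ECAM channel attention
#'
#' SE-style excitation of the enhanced descriptor:
#' \eqn{P_C = \sigma(W_2\,\delta(W_1 z'))}; exactly one MLP evaluation per
#' forward pass.
#'
#' @inheritParams cam_attention
#' @param max_gate `"sigmoid"` (the ECAM gate) or `"one"` which forces the
#'   gate to 1 and reduces the operator bitwise to the SE path on the same
#'   weights.
#' @return channel attention matrix `(N, C)`.
#' @export
ecam_attention <- function(x, w, max_gate = c("sigmoid", "one")) {
  max_gate <- match.arg(max_gate)
  z <- if (max_gate == "sigmoid") ecam_descriptor(x) else global_average_pool(x)
  se_excitation(z, w)
}

#' Adaptive ECA kernel size
#'
#' Nearest odd integer to \eqn{\log_2(C)/2 + 1/2}; gives k = 5 at C = 512.
#'
#' @param C channel count.
#' @return odd integer kernel size.
#' @export
eca_kernel_size <- function(C) {
  t <- log2(C) / 2 + 0.5
  k <- round(t)
  if (k %% 2 == 0) k <- k + ifelse(t >= k, 1, -1)
  max(1L, as.integer(k))
}

#' ECA channel attention (baseline)
#'
#' Efficient channel attention: a 1-D convolution of odd size `kernel` slides
#' over the avg-pooled descriptor treated as a sequence (zero padding
#' `(kernel-1)/2`, no bias), followed by a sigmoid.
#'
#' @inheritParams global_average_pool
#' @param weights numeric vector of length `kernel`; random small weights if
#'   omitted.
#' @param kernel odd kernel size; defaults to the adaptive rule
#'   [eca_kernel_size()].
#' @return channel attention matrix `(N, C)`.
#' @export
eca_attention <- function(x, weights = NULL, kernel = NULL) {
  d <- check_feature_map(x)
  if (is.null(kernel)) kernel <- eca_kernel_size(d[2])
  if (kernel %% 2 == 0) stop("ECA kernel must be odd")
  if (is.null(weights)) weights <- rnorm(kernel, sd = 0.05)
  stopifnot(length(weights) == kernel)
  z <- global_average_pool(x)
  C <- d[2]; pad <- (kernel - 1) / 2
  zp <- cbind(matrix(0, d[1], pad), z, matrix(0, d[1], pad))
  out <- matrix(0, d[1], C)
  for (u in seq_len(kernel)) out <- out + weights[u] * zp[, u:(u + C - 1), drop = FALSE]
  sigmoid(out)
}

#' Spatial attention weights
#'
#' The `kernel x kernel` convolution (2 input channels: channel-wise mean and
#' max maps; 1 output channel; with bias) used by the spatial attention stage.
#'
#' @param kernel odd kernel size (default 7).
#' @param w array `(1, 2, kernel, kernel)`; random small weights if omitted.
#' @param b scalar bias.
#' @return object of class `sam_weights`.
#' @export
sam_weights <- function(kernel = 7, w = NULL, b = 0) {
  if (kernel %% 2 == 0) stop("spatial attention kernel must be odd")
  if (is.null(w)) w <- array(rnorm(2 * kernel * kernel, sd = 0.05),
                             c(1, 2, kernel, kernel))
  stopifnot(all(dim(w) == c(1, 2, kernel, kernel)), length(b) == 1)
  structure(list(w = w, b = b, kernel = kernel), class = "sam_weights")
}

#' Spatial attention map
#'
#' \eqn{P_S = \sigma(f^{k\times k}([F^S_{avg}(T); F^S_{max}(T)]))}: the
#' channel-wise mean and max of the (channel-refined) feature map are stacked
#' as a 2-channel map, convolved with zero padding `(k-1)/2` so H, W are
#' preserved, and passed through a sigmoid.
#'
#' @param t feature map `(N, C, H, W)` (typically already refined by channel
#'   attention).
#' @param w [sam_weights()].
#' @return spatial attention array `(N, 1, H, W)` with entries in (0,1).
#' @export
spatial_attention <- function(t, w) {
  d <- check_feature_map(t)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  k <- w$kernel; pad <- (k - 1) / 2
  # channel-wise mean / max maps: (N, H, W)
  avg <- apply(t, c(1, 3, 4), mean)
  mx  <- apply(t, c(1, 3, 4), max)
  acc <- array(w$b, c(N, H, W))
  padded <- function(a) {
    p <- array(0, c(N, H + 2 * pad, W + 2 * pad))
    p[, pad + seq_len(H), pad + seq_len(W)] <- a
    p
  }
  pa <- padded(avg); pm <- padded(mx)
  for (u in seq_len(k)) for (v in seq_len(k)) {
    sa <- pa[, (u - 1) + seq_len(H), (v - 1) + seq_len(W), drop = FALSE]
    sm <- pm[, (u - 1) + seq_len(H), (v - 1) + seq_len(W), drop = FALSE]
    acc <- acc + w$w[1, 1, u, v] * array(sa, c(N, H, W)) +
      w$w[1, 2, u, v] * array(sm, c(N, H, W))
  }
  array(sigmoid(acc), c(N, 1, H, W))
}

#' Apply channel attention gates
#'
#' Rescales every channel by its gate: \eqn{o_c(i,j) = p_c\, x_c(i,j)}.
#'
#' @inheritParams global_average_pool
#' @param p channel attention `(N, C)` matrix (or length-`C` vector).
#' @return feature map of the same shape as `x`.
#' @export
apply_channel_attention <- function(x, p) {
  d <- check_feature_map(x)
  if (is.null(dim(p))) p <- matrix(p, d[1], length(p), byrow = TRUE)
  if (ncol(p) != d[2] || nrow(p) != d[1])
    stop("channel attention shape (", nrow(p), ",", ncol(p),
         ") does not match feature map (", d[1], ",", d[2], ")")
  x * array(p, dim(x))  # (N,C) recycles over H, W in column-major order
}

#' Apply spatial attention gates
#'
#' Rescales every spatial position by its gate across all channels.
#'
#' @inheritParams global_average_pool
#' @param s spatial attention `(N, 1, H, W)` array.
#' @return feature map of the same shape as `x`.
#' @export
apply_spatial_attention <- function(x, s) {
  d <- check_feature_map(x)
  if (!all(dim(s) == c(d[1], 1, d[3], d[4])))
    stop("spatial attention shape does not match feature map")
  g <- array(0, d)
  for (c in seq_len(d[2])) g[, c, , ] <- s[, 1, , ]
  x * g
}

#' Attention encoder configuration
#'
#' @param kind one of `"none"`, `"se"`, `"eca"`, `"cam"`, `"ecam"`, `"sam"`,
#'   `"cbam"`, `"ecbam"`.
#' @param channels encoder channel count C (default 512).
#' @param reduction MLP reduction ratio r (default 16); must divide
#'   `channels`.
#' @param spatial_kernel odd spatial-attention kernel (default 7).
#' @param mlp_bias keep MLP biases (default TRUE).
#' @return object of class `attention_config`.
#' @export
attention_config <- function(kind = "ecbam", channels = 512, reduction = 16,
                             spatial_kernel = 7, mlp_bias = TRUE) {
  kinds <- c("none", "se", "eca", "cam", "ecam", "sam", "cbam", "ecbam")
  if (!kind %in% kinds)
    stop("unknown attention kind '", kind, "'")
  if (spatial_kernel %% 2 == 0) stop("spatial_kernel must be odd")
  if (kind %in% c("se", "cam", "ecam", "cbam", "ecbam") &&
      channels %% reduction != 0)
    stop("reduction must divide channels")
  structure(list(kind = kind, channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 mlp_bias = isTRUE(mlp_bias)),
            class = "attention_config")
}

#' Sequential channel + spatial attention forward (CBAM / ECBAM)
#'
#' Applies the channel stage (ECAM for `kind = "ecbam"`, CAM for
#' `kind = "cbam"`) to produce the refined map T, then rescales T by its
#' spatial attention map. Shape `(N, C, H, W)` is preserved.
#'
#' @inheritParams global_average_pool
#' @param cfg [attention_config()] with kind `"cbam"` or `"ecbam"`.
#' @param mlp [mlp_weights()] for the channel stage.
#' @param sam [sam_weights()] for the spatial stage.
#' @return refined feature map, same shape as `x`.
#' @export
ecbam_forward <- function(x, cfg, mlp, sam) {
  if (!cfg$kind %in% c("cbam", "ecbam"))
    stop("ecbam_forward needs kind 'cbam' or 'ecbam'")
  p <- if (cfg$kind == "ecbam") ecam_attention(x, mlp) else cam_attention(x, mlp)
  t <- apply_channel_attention(x, p)
  apply_spatial_attention(t, spatial_attention(t, sam))
}

#' Exact attention parameter count
#'
#' Trainable-parameter count of an attention encoder, by enumerating its
#' weight shapes: bottleneck MLP with biases for SE/CAM/ECAM (CAM's MLP is
#' shared across branches, so counted once), `2 k^2 + 1` for the spatial conv
#' (with bias), the adaptive-size 1-D conv without bias for ECA.
#'
#' @param cfg [attention_config()].
#' @return integer parameter count.
#' @export
attention_param_count <- function(cfg) {
  C <- cfg$channels; r <- cfg$reduction; k <- cfg$spatial_kernel
  mlp <- function() {
    n <- 2L * C * (C %/% r)
    if (cfg$mlp_bias) n <- n + (C %/% r) + C
    n
  }
  sam <- function() 2L * k * k + 1L
  switch(cfg$kind,
         none = 0L,
         se   = mlp(),
         cam  = mlp(),
         ecam = mlp(),
         eca  = as.integer(eca_kernel_size(C)),
         sam  = sam(),
         cbam = mlp() + sam(),
         ecbam = mlp() + sam(),
         stop("unknown attention kind"))
}
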