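# Brute-force scalar oracles, kept deliberately naive and independent of the
# package's vectorized / compiled implementations.

oracle_gap <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1], d[2])
  for (n in seq_len(d[1])) for (c in seq_len(d[2])) {
    s <- 0
    for (i in seq_len(d[3])) for (j in seq_len(d[4])) s <- s + x[n, c, i, j]
    out[n, c] <- s / (d[3] * d[4])
  }
  out
}

oracle_gmp <- function(x) {
  d <- dim(x)
  out <- matrix(-Inf, d[1], d[2])
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    for (i in seq_len(d[3])) for (j in seq_len(d[4]))
      if (x[n, c, i, j] > out[n, c]) out[n, c] <- x[n, c, i, j]
  out
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# scalar evaluation of the excitation MLP for one descriptor vector
oracle_mlp <- function(z, w) {
  Cr <- nrow(w$W1); C <- ncol(w$W1)
  h <- numeric(Cr)
  for (i in seq_len(Cr)) {
    acc <- w$b1[i]
    for (j in seq_len(C)) acc <- acc + w$W1[i, j] * z[j]
    h[i] <- max(0, acc)
  }
  out <- numeric(C)
  for (i in seq_len(C)) {
    acc <- w$b2[i]
    for (j in seq_len(Cr)) acc <- acc + w$W2[i, j] * h[j]
    out[i] <- acc
  }
  out
}

oracle_se <- function(z, w) {
  t(apply(z, 1, function(zz) oracle_sigmoid(oracle_mlp(zz, w))))
}

oracle_cam <- function(x, w) {
  z <- oracle_gap(x); m <- oracle_gmp(x)
  out <- matrix(0, nrow(z), ncol(z))
  for (n in seq_len(nrow(z)))
    out[n, ] <- oracle_sigmoid(oracle_mlp(z[n, ], w) + oracle_mlp(m[n, ], w))
  out
}

oracle_ecam_desc <- function(x) oracle_sigmoid(oracle_gmp(x)) * oracle_gap(x)

oracle_eca <- function(x, weights) {
  z <- oracle_gap(x)
  k <- length(weights); pad <- (k - 1) / 2
  out <- matrix(0, nrow(z), ncol(z))
  for (n in seq_len(nrow(z))) for (c in seq_len(ncol(z))) {
    acc <- 0
    for (u in seq_len(k)) {
      cc <- c + u - 1 - pad
      if (cc >= 1 && cc <= ncol(z)) acc <- acc + weights[u] * z[n, cc]
    }
    out[n, c] <- oracle_sigmoid(acc)
  }
  out
}

# quadruple-loop direct convolution for the spatial attention stage
oracle_sam <- function(t, w) {
  d <- dim(t)
  k <- w$kernel; pad <- (k - 1) / 2
  out <- array(0, c(d[1], 1, d[3], d[4]))
  for (n in seq_len(d[1])) for (i in seq_len(d[3])) for (j in seq_len(d[4])) {
    acc <- w$b
    for (u in seq_len(k)) for (v in seq_len(k)) {
      ii <- i + u - 1 - pad; jj <- j + v - 1 - pad
      if (ii >= 1 && ii <= d[3] && jj >= 1 && jj <= d[4]) {
        avg <- mean(t[n, , ii, jj])
        mx <- max(t[n, , ii, jj])
        acc <- acc + w$w[1, 1, u, v] * avg + w$w[1, 2, u, v] * mx
      }
    }
    out[n, 1, i, j] <- oracle_sigmoid(acc)
  }
  out
}

oracle_apply_channel <- function(x, p) {
  d <- dim(x)
  out <- x
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    for (i in seq_len(d[3])) for (j in seq_len(d[4]))
      out[n, c, i, j] <- p[n, c] * x[n, c, i, j]
  out
}

# direct (quadruple-loop) 2-D convolution: x (N,Ci,H,W), w (Co,Ci,kh,kw)
oracle_conv2d <- function(x, w, bias = NULL, stride = 1, pad = 0, dil = 1) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[3] + 2 * pad - dil * (wd[3] - 1) - 1) %/% stride + 1
  Wo <- (d[4] + 2 * pad - dil * (wd[4] - 1) - 1) %/% stride + 1
  out <- array(0, c(d[1], wd[1], Ho, Wo))
  for (n in seq_len(d[1])) for (co in seq_len(wd[1]))
    for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
      acc <- if (is.null(bias)) 0 else bias[co]
      for (ci in seq_len(wd[2])) for (u in seq_len(wd[3])) for (v in seq_len(wd[4])) {
        ii <- (oi - 1) * stride - pad + (u - 1) * dil + 1
        jj <- (oj - 1) * stride - pad + (v - 1) * dil + 1
        if (ii >= 1 && ii <= d[3] && jj >= 1 && jj <= d[4])
          acc <- acc + w[co, ci, u, v] * x[n, ci, ii, jj]
      }
      out[n, co, oi, oj] <- acc
    }
  out
}

oracle_dwconv <- function(x, w, stride = 1, pad = 0) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[3] + 2 * pad - wd[2]) %/% stride + 1
  Wo <- (d[4] + 2 * pad - wd[3]) %/% stride + 1
  out <- array(0, c(d[1], d[2], Ho, Wo))
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
      acc <- 0
      for (u in seq_len(wd[2])) for (v in seq_len(wd[3])) {
        ii <- (oi - 1) * stride - pad + u
        jj <- (oj - 1) * stride - pad + v
        if (ii >= 1 && ii <= d[3] && jj >= 1 && jj <= d[4])
          acc <- acc + w[c, u, v] * x[n, c, ii, jj]
      }
      out[n, c, oi, oj] <- acc
    }
  out
}

# O(n^2) greedy NMS oracle (per class, descending score)
oracle_nms <- function(records, thr) {
  keep <- integer(0)
  for (cl in unique(records$category)) {
    idx <- which(records$category == cl)
    idx <- idx[order(-records$score[idx])]
    chosen <- integer(0)
    for (i in idx) {
      ok <- TRUE
      for (j in chosen) {
        bi <- as.numeric(records[i, c("x", "y", "w", "h")])
        bj <- as.numeric(records[j, c("x", "y", "w", "h")])
        ix <- max(0, min(bi[1] + bi[3], bj[1] + bj[3]) - max(bi[1], bj[1]))
        iy <- max(0, min(bi[2] + bi[4], bj[2] + bj[4]) - max(bi[2], bj[2]))
        inter <- ix * iy
        iou <- inter / (bi[3] * bi[4] + bj[3] * bj[4] - inter)
        if (iou > thr) { ok <- FALSE; break }
      }
      if (ok) chosen <- c(chosen, i)
    }
    keep <- c(keep, chosen)
  }
  sort(keep)
}

random_feature_map <- function(seed, d = c(4, 8, 5, 5)) {
  set.seed(seed)
  array(rnorm(prod(d)), d)
}
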