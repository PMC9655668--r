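# Anchor generation, target assignment, losses, box coding and NMS.
# All boxes use COCO xywh pixel convention (0-based, half-open) unless a
# function documents otherwise; internal geometry converts to corner form.

xywh_to_corners <- function(b) {
  cbind(x1 = b[, 1], y1 = b[, 2], x2 = b[, 1] + b[, 3], y2 = b[, 2] + b[, 4])
}

corners_to_xywh <- function(b) {
  cbind(x = b[, 1], y = b[, 2], w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' Pairwise box IoU
#'
#' @param a,b box matrices in xywh (columns x, y, w, h).
#' @return `nrow(a) x nrow(b)` matrix of intersection-over-union values.
#' @export
box_iou <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ca <- xywh_to_corners(a); cb <- xywh_to_corners(b)
  ix <- pmax(outer(ca[, 3], cb[, 3], pmin) - outer(ca[, 1], cb[, 1], pmax), 0)
  iy <- pmax(outer(ca[, 4], cb[, 4], pmin) - outer(ca[, 2], cb[, 2], pmax), 0)
  inter <- ix * iy
  area_a <- a[, 3] * a[, 4]
  area_b <- b[, 3] * b[, 4]
  un <- outer(area_a, area_b, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Generate the anchor set
#'
#' Square anchors of side 32, 64, 128, 256, 512 centered on every cell of the
#' stride-32 grid, in input-image pixel coordinates; 13 x 13 x A anchors at
#' image size 416.
#'
#' @param A anchors per cell (default 5, one per size).
#' @param stride feature stride (32).
#' @param image_size input image side; must be divisible by `stride`.
#' @return data.frame with columns `cx`, `cy`, `w`, `h` and attribute `grid`;
#'   rows ordered cell-major (row, then column) with the anchor index fastest.
#' @export
generate_anchors <- function(A = 5, stride = 32, image_size = 416) {
  if (image_size %% stride != 0)
    stop("image_size must be divisible by stride")
  g <- image_size %/% stride
  sizes <- c(32, 64, 128, 256, 512)[seq_len(A)]
  cells_y <- rep(seq_len(g), each = g * A)
  cells_x <- rep(rep(seq_len(g), each = A), g)
  an <- data.frame(cx = (cells_x - 1) * stride + stride / 2,
                   cy = (cells_y - 1) * stride + stride / 2,
                   w = rep(sizes, g * g), h = rep(sizes, g * g))
  attr(an, "grid") <- g
  an
}

anchors_xywh <- function(an) {
  cbind(an$cx - an$w / 2, an$cy - an$h / 2, an$w, an$h)
}

#' Encode / decode boxes against anchors
#'
#' Standard center/size delta coding: `dx = (gx - ax)/aw`, `dy = (gy -
#' ay)/ah`, `dw = log(gw/aw)`, `dh = log(gh/ah)` where `(ax, ay)` are anchor
#' centers. `decode_boxes(encode_boxes(...))` is the identity.
#'
#' @param anchors anchor data.frame from [generate_anchors()] (or its rows).
#' @param boxes matrix of boxes in xywh.
#' @param deltas matrix of deltas (`dx`, `dy`, `dw`, `dh`).
#' @return matrix of deltas (encode) or xywh boxes (decode).
#' @export
encode_boxes <- function(anchors, boxes) {
  boxes <- as.matrix(boxes)
  if (any(boxes[, 3] <= 0 | boxes[, 4] <= 0))
    stop("boxes must have positive width and height")
  gx <- boxes[, 1] + boxes[, 3] / 2
  gy <- boxes[, 2] + boxes[, 4] / 2
  cbind(dx = (gx - anchors$cx) / anchors$w,
        dy = (gy - anchors$cy) / anchors$h,
        dw = log(boxes[, 3] / anchors$w),
        dh = log(boxes[, 4] / anchors$h))
}

# smooth symmetric saturation: identity on [-knee, knee], tanh approach to
# +/- lim beyond; keeps decode bounded while its derivative never vanishes
saturate_delta <- function(d, lim, knee = 2) {
  over <- abs(d) > knee
  d[over] <- sign(d[over]) *
    (knee + (lim - knee) * tanh((abs(d[over]) - knee) / (lim - knee)))
  d
}

saturate_grad <- function(d, lim, knee = 2) {
  g <- rep(1, length(d))
  over <- abs(d) > knee
  g[over] <- 1 - tanh((abs(d[over]) - knee) / (lim - knee))^2
  g
}

delta_limits <- function() c(xy = 4, wh = log(1000 / 16))

#' @param saturate apply the smooth saturation to the deltas before
#'   decoding (used by training and inference so network outputs decode to
#'   bounded boxes); `FALSE` (default) is the pure coder, for which
#'   `decode_boxes(anchors, encode_boxes(anchors, b))` is exactly `b`.
#' @rdname encode_boxes
#' @export
decode_boxes <- function(anchors, deltas, saturate = FALSE) {
  deltas <- as.matrix(deltas)
  if (saturate) {
    lim <- delta_limits()
    deltas[, 1] <- saturate_delta(deltas[, 1], lim["xy"])
    deltas[, 2] <- saturate_delta(deltas[, 2], lim["xy"])
    deltas[, 3] <- saturate_delta(deltas[, 3], lim["wh"])
    deltas[, 4] <- saturate_delta(deltas[, 4], lim["wh"])
  }
  w <- anchors$w * exp(pmin(deltas[, 3], log(1e4)))
  h <- anchors$h * exp(pmin(deltas[, 4], log(1e4)))
  cx <- anchors$cx + deltas[, 1] * anchors$w
  cy <- anchors$cy + deltas[, 2] * anchors$h
  cbind(x = cx - w / 2, y = cy - h / 2, w = w, h = h)
}

#' Uniform anchor matching
#'
#' Each ground-truth box is assigned its `k` nearest anchors by center L2
#' distance (positives). Unmatched anchors whose IoU with any ground truth
#' exceeds `iou_ignore` are ignored, and positives whose IoU with their own
#' ground truth is below `iou_min` are demoted to ignored.
#'
#' @param gt_boxes ground-truth boxes in xywh (matrix; 0 rows allowed).
#' @param anchors anchor set from [generate_anchors()].
#' @param k positives per ground truth (default 4).
#' @param iou_ignore,iou_min ignore thresholds (defaults 0.7 / 0.15).
#' @return list: `labels` (length n_anchors: 0 negative, -1 ignored, g > 0 the
#'   matched ground-truth index), `n_pos`.
#' @export
uniform_match <- function(gt_boxes, anchors, k = 4, iou_ignore = 0.7,
                          iou_min = 0.15) {
  n <- nrow(anchors)
  labels <- integer(n)
  gt_boxes <- as.matrix(gt_boxes)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0)
    return(list(labels = labels, n_pos = 0L))
  ng <- nrow(gt_boxes)
  gcx <- gt_boxes[, 1] + gt_boxes[, 3] / 2
  gcy <- gt_boxes[, 2] + gt_boxes[, 4] / 2
  d2 <- outer(anchors$cx, gcx, `-`)^2 + outer(anchors$cy, gcy, `-`)^2
  # k nearest anchors per gt, ties (co-centered anchors of different sizes)
  # broken in favour of the anchor whose scale best matches the box
  assigned_d <- rep(Inf, n)
  for (g in seq_len(ng)) {
    size_mismatch <- abs(log(anchors$w / gt_boxes[g, 3])) +
      abs(log(anchors$h / gt_boxes[g, 4]))
    near <- order(d2[, g], size_mismatch)[seq_len(min(k, n))]
    take <- d2[near, g] < assigned_d[near]
    labels[near[take]] <- g
    assigned_d[near[take]] <- d2[near[take], g]
  }
  iou <- box_iou(anchors_xywh(anchors), gt_boxes)
  maxi <- apply(iou, 1, max)
  labels[labels == 0L & maxi > iou_ignore] <- -1L
  pos <- which(labels > 0L)
  own <- iou[cbind(pos, labels[pos])]
  labels[pos[own < iou_min]] <- -1L
  list(labels = labels, n_pos = sum(labels > 0L))
}

#' Focal loss
#'
#' \eqn{-\alpha (1-p)^\gamma \log p} for positives and the symmetric
#' \eqn{-(1-\alpha) p^\gamma \log(1-p)} for negatives.
#'
#' @param p predicted probabilities in (0,1); values outside are clamped with
#'   a warning.
#' @param y binary targets (0/1).
#' @param alpha,gamma focusing parameters (defaults 0.25, 2).
#' @param reduce `"sum"`, `"mean"` or `"none"`.
#' @return loss value(s).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2, reduce = "sum") {
  if (any(p <= 0 | p >= 1)) {
    warning("focal_loss: probabilities outside (0,1) clamped")
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  l <- ifelse(y > 0,
              -alpha * (1 - p)^gamma * log(p),
              -(1 - alpha) * p^gamma * log(1 - p))
  switch(reduce, sum = sum(l), mean = mean(l), none = l)
}

#' Generalized IoU and GIoU loss
#'
#' `giou_loss(b1, b2) = 1 - GIoU(b1, b2)`, in `[0, 2]`.
#'
#' @param b1,b2 boxes in xywh (vectors or row-aligned matrices).
#' @return numeric GIoU values / losses.
#' @export
giou <- function(b1, b2) {
  b1 <- matrix(as.numeric(as.matrix(b1)), ncol = 4)
  b2 <- matrix(as.numeric(as.matrix(b2)), ncol = 4)
  if (any(b1[, 3] <= 0 | b1[, 4] <= 0 | b2[, 3] <= 0 | b2[, 4] <= 0))
    stop("degenerate box: width and height must be positive")
  c1 <- xywh_to_corners(b1); c2 <- xywh_to_corners(b2)
  iw <- pmax(pmin(c1[, 3], c2[, 3]) - pmax(c1[, 1], c2[, 1]), 0)
  ih <- pmax(pmin(c1[, 4], c2[, 4]) - pmax(c1[, 2], c2[, 2]), 0)
  inter <- iw * ih
  un <- b1[, 3] * b1[, 4] + b2[, 3] * b2[, 4] - inter
  ew <- pmax(c1[, 3], c2[, 3]) - pmin(c1[, 1], c2[, 1])
  eh <- pmax(c1[, 4], c2[, 4]) - pmin(c1[, 2], c2[, 2])
  enc <- ew * eh
  unname(inter / un - (enc - un) / enc)
}

#' @rdname giou
#' @export
giou_loss <- function(b1, b2) 1 - giou(b1, b2)

#' Greedy non-maximum suppression
#'
#' Per-class greedy suppression by descending score: a detection is dropped
#' when it overlaps an already-kept same-class detection above
#' `iou_threshold`.
#'
#' @param records data.frame with columns `score`, `category` (or
#'   `category_id`) and `x`, `y`, `w`, `h`.
#' @param iou_threshold IoU threshold in (0, 1], default 0.6.
#' @return the surviving rows, ordered by descending score.
#' @export
nms <- function(records, iou_threshold = 0.6) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be in (0, 1]")
  if (nrow(records) == 0) return(records)
  cls_col <- if ("category" %in% names(records)) "category" else "category_id"
  keep_all <- integer(0)
  for (cl in unique(records[[cls_col]])) {
    idx <- which(records[[cls_col]] == cl)
    idx <- idx[order(-records$score[idx])]
    boxes <- as.matrix(records[idx, c("x", "y", "w", "h")])
    keep <- logical(length(idx))
    for (i in seq_along(idx)) {
      if (i == 1) { keep[1] <- TRUE; next }
      kept <- which(keep)
      ov <- box_iou(boxes[i, , drop = FALSE], boxes[kept, , drop = FALSE])
      keep[i] <- all(ov <= iou_threshold)
    }
    keep_all <- c(keep_all, idx[keep])
  }
  out <- records[keep_all, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}
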