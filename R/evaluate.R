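# Inference, MS-COCO protocol metrics and attention-map visualization.

#' Run the detector on one image
#'
#' Resizes the image to the evaluation size, runs the network in eval mode,
#' decodes boxes against the anchor set, applies the score floor and
#' per-class NMS, and returns detections in the *original* image coordinate
#' space. The ranking score of an (anchor, class) pair is
#' `sigmoid(class logit) * sigmoid(objectness logit)`.
#'
#' @param model an [encanet()] model.
#' @param image `(H, W, 3)` array in `[0, 1]`, or a dataset record carrying
#'   one.
#' @param score_floor minimum score before NMS (default 0.05).
#' @param nms_threshold NMS IoU threshold (default 0.6).
#' @param max_det maximum detections returned (default 100).
#' @param eval_size input side for the network; defaults to the model's
#'   configured image size.
#' @param image_id id copied into the result (default 1, or the record's).
#' @return data.frame: `image_id`, `category_id`, `category`, `score`, `x`,
#'   `y`, `w`, `h` (COCO xywh pixels).
#' @export
detect <- function(model, image, score_floor = 0.05, nms_threshold = 0.6,
                   max_det = 100, eval_size = NULL, image_id = 1L) {
  if (is.list(image)) { image_id <- image$image_id; image <- image$image }
  H0 <- dim(image)[1]; W0 <- dim(image)[2]
  S <- if (is.null(eval_size)) model$config$image_size else as.integer(eval_size)
  img <- if (H0 != S || W0 != S) resize_image(image, S, S) else image
  x <- array(0, c(1, 3, S, S))
  x[1, , , ] <- aperm(normalize_image(img), c(3, 1, 2))
  out <- encanet_forward(model, x, training = FALSE)$values
  K <- model$config$num_classes; A <- model$config$anchors_per_cell
  anchors <- generate_anchors(A, model$config$stride, S)
  cl <- head_to_mat(out$cls, 1, K)
  bx <- head_to_mat(out$box, 1, 4)
  ob <- head_to_mat(out$obj, 1, 1)[, 1]
  p <- sigmoid(cl) * sigmoid(ob)
  hits <- which(p >= score_floor, arr.ind = TRUE)
  cats <- synthetic_categories()
  if (nrow(hits) == 0)
    return(data.frame(image_id = integer(0), category_id = integer(0),
                      category = character(0), score = numeric(0),
                      x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0)))
  boxes <- decode_boxes(anchors[hits[, 1], ], bx[hits[, 1], , drop = FALSE],
                        saturate = TRUE)
  # clip to the network input frame, then rescale to original pixels
  x1 <- pmin(pmax(boxes[, 1], 0), S); y1 <- pmin(pmax(boxes[, 2], 0), S)
  x2 <- pmin(pmax(boxes[, 1] + boxes[, 3], 0), S)
  y2 <- pmin(pmax(boxes[, 2] + boxes[, 4], 0), S)
  df <- data.frame(image_id = image_id, category_id = hits[, 2],
                   category = cats$name[match(hits[, 2], cats$id)],
                   score = p[hits],
                   x = x1 * W0 / S, y = y1 * H0 / S,
                   w = (x2 - x1) * W0 / S, h = (y2 - y1) * H0 / S)
  df <- df[df$w > 1e-3 & df$h > 1e-3, , drop = FALSE]
  df <- nms(df, nms_threshold)
  head(df, max_det)
}

#' @export
predict.encanet <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata$image))
    newdata <- list(newdata)
  if (is.array(newdata))
    return(detect(object, newdata, ...))
  do.call(rbind, lapply(newdata, function(r) detect(object, r, ...)))
}

# ---- COCO-protocol metrics ----------------------------------------------

coco_area_ranges <- function()
  list(all = c(0, Inf), small = c(0, 32^2), medium = c(32^2, 96^2),
       large = c(96^2, Inf))

# per (image, category, area range) matching at every IoU threshold,
# following the reference greedy protocol (ignored ground truths matched
# last; unmatched detections outside the area range ignored)
coco_eval_img <- function(dt, gt, iou_thrs, arng, max_det) {
  if (nrow(dt) == 0 && nrow(gt) == 0) return(NULL)
  gt_ig <- gt$area < arng[1] | gt$area > arng[2]
  ord_g <- order(gt_ig)
  gt <- gt[ord_g, , drop = FALSE]; gt_ig <- gt_ig[ord_g]
  ord_d <- order(-dt$score, method = "radix")
  dt <- dt[head(ord_d, max_det), , drop = FALSE]
  nT <- length(iou_thrs); nd <- nrow(dt); ng <- nrow(gt)
  iou <- if (nd && ng) box_iou(as.matrix(dt[, c("x", "y", "w", "h")]),
                               as.matrix(gt[, c("x", "y", "w", "h")]))
         else matrix(0, nd, ng)
  dtm <- matrix(0L, nT, nd); dt_ig <- matrix(FALSE, nT, nd)
  gtm <- matrix(0L, nT, ng)
  for (t in seq_len(nT)) {
    thr <- iou_thrs[t]
    for (d in seq_len(nd)) {
      best <- thr - 1e-10; m <- 0L
      for (g in seq_len(ng)) {
        if (gtm[t, g] > 0L) next
        if (m > 0L && !gt_ig[m] && gt_ig[g]) break
        if (iou[d, g] < best) next
        best <- iou[d, g]; m <- g
      }
      if (m > 0L) {
        dtm[t, d] <- m; gtm[t, m] <- d
        dt_ig[t, d] <- gt_ig[m]
      } else {
        a <- dt$w[d] * dt$h[d]
        dt_ig[t, d] <- a < arng[1] | a > arng[2]
      }
    }
  }
  list(score = dt$score, dtm = dtm, dt_ig = dt_ig,
       npig = sum(!gt_ig))
}

#' MS-COCO detection metrics
#'
#' Computes the COCO-protocol average precision (101-point interpolation,
#' IoU thresholds 0.5 to 0.95 in steps of 0.05, small/medium/large area
#' splits at 32^2 / 96^2 pixels, up to 100 detections per image). Categories
#' without ground truth are excluded from the means. Values are on the
#' conventional 0-100 scale.
#'
#' @param dt detections data.frame (`image_id`, `category_id`, `score`, `x`,
#'   `y`, `w`, `h`).
#' @param gt ground-truth data.frame (`image_id`, `category_id`, `x`, `y`,
#'   `w`, `h`).
#' @param max_det detections per image cap (default 100).
#' @return list with `AP`, `AP50`, `AP75`, `APS`, `APM`, `APL`.
#' @export
coco_eval <- function(dt, gt, max_det = 100) {
  iou_thrs <- seq(0.5, 0.95, 0.05)
  rec_thrs <- seq(0, 1, 0.01)
  gt$area <- gt$w * gt$h
  cat_ids <- sort(unique(gt$category_id))
  img_ids <- unique(c(dt$image_id, gt$image_id))
  areas <- coco_area_ranges()
  # ap[t, r_area, cat]
  ap <- array(NA_real_, c(length(iou_thrs), length(areas), length(cat_ids)))
  for (ci in seq_along(cat_ids)) {
    for (ai in seq_along(areas)) {
      evs <- lapply(img_ids, function(im)
        coco_eval_img(dt[dt$image_id == im & dt$category_id == cat_ids[ci], , drop = FALSE],
                      gt[gt$image_id == im & gt$category_id == cat_ids[ci], , drop = FALSE],
                      iou_thrs, areas[[ai]], max_det))
      evs <- evs[!vapply(evs, is.null, TRUE)]
      if (!length(evs)) next
      npig <- sum(vapply(evs, `[[`, 0, "npig"))
      if (npig == 0) next
      scores <- unlist(lapply(evs, `[[`, "score"))
      ord <- order(-scores, method = "radix")
      for (t in seq_along(iou_thrs)) {
        dtm <- unlist(lapply(evs, function(e) e$dtm[t, ]))[ord]
        ig <- unlist(lapply(evs, function(e) e$dt_ig[t, ]))[ord]
        tp <- cumsum(dtm > 0 & !ig)
        fp <- cumsum(dtm == 0 & !ig)
        rc <- tp / npig
        pr <- tp / pmax(tp + fp, .Machine$double.eps)
        # interpolate: precision envelope from the right
        if (length(pr) > 1)
          for (i in (length(pr) - 1):1) pr[i] <- max(pr[i], pr[i + 1])
        q <- vapply(rec_thrs, function(r) {
          i <- which(rc >= r)[1]
          if (is.na(i)) 0 else pr[i]
        }, 0)
        ap[t, ai, ci] <- mean(q)
      }
    }
  }
  m <- function(ts, ai) {
    v <- ap[ts, ai, , drop = FALSE]
    if (all(is.na(v))) 0 else mean(v, na.rm = TRUE) * 100
  }
  list(AP = m(seq_along(iou_thrs), 1),
       AP50 = m(which(abs(iou_thrs - 0.5) < 1e-9), 1),
       AP75 = m(which(abs(iou_thrs - 0.75) < 1e-9), 1),
       APS = m(seq_along(iou_thrs), 2),
       APM = m(seq_along(iou_thrs), 3),
       APL = m(seq_along(iou_thrs), 4))
}

records_to_gt <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    if (nrow(r$boxes) == 0) return(NULL)
    data.frame(image_id = r$image_id, category_id = r$category_ids,
               x = r$boxes[, 1], y = r$boxes[, 2],
               w = r$boxes[, 3], h = r$boxes[, 4])
  }))
}

#' Evaluate a detector on a record set
#'
#' Runs inference (score floor 0.05, NMS 0.6) on every record and scores the
#' detections with the COCO metrics.
#'
#' @param model an [encanet()] model.
#' @param records dataset records with images and ground-truth boxes.
#' @param eval_size network input side (defaults to the model's configured
#'   size).
#' @param ... passed to [detect()].
#' @return list with `metrics` (from [coco_eval()]) and the `detections`
#'   data.frame.
#' @export
evaluate_encanet <- function(model, records, eval_size = NULL, ...) {
  dts <- lapply(records, function(r) detect(model, r, eval_size = eval_size, ...))
  dt <- do.call(rbind, dts)
  gt <- records_to_gt(records)
  list(metrics = coco_eval(dt, gt), detections = dt)
}

# ---- attention maps ------------------------------------------------------

# min-max to [0,1]; a degenerate (constant) map maps to all zeros
normalize_heatmap <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Attention heatmap at a tap point
#'
#' Channel-mean of the feature map tapped `after_backbone` or
#' `after_encoder`, min-max normalized to `[0, 1]` (a constant map
#' normalizes to all zeros), bilinearly upsampled to the image size, plus an
#' overlay rendering on the input image.
#'
#' @param model an [encanet()] model.
#' @param image `(H, W, 3)` array in `[0, 1]` (or a record).
#' @param tap_point `"after_backbone"` or `"after_encoder"`.
#' @param eval_size network input side (defaults to the model's configured
#'   size).
#' @return list with `map` (H x W matrix in `[0, 1]`) and `overlay`
#'   (H x W x 3 array).
#' @export
attention_map <- function(model, image, tap_point = "after_encoder",
                          eval_size = NULL) {
  if (!tap_point %in% c("after_backbone", "after_encoder"))
    stop("unknown tap point '", tap_point, "'")
  if (is.list(image)) image <- image$image
  H0 <- dim(image)[1]; W0 <- dim(image)[2]
  S <- if (is.null(eval_size)) model$config$image_size else as.integer(eval_size)
  img <- if (H0 != S || W0 != S) resize_image(image, S, S) else image
  x <- array(0, c(1, 3, S, S))
  x[1, , , ] <- aperm(normalize_image(img), c(3, 1, 2))
  v <- encanet_forward(model, x, training = FALSE, taps = tap_point)$values[[1]]
  fm <- v[1, , , ]                       # (C, H', W')
  m <- normalize_heatmap(apply(fm, c(2, 3), mean))
  up <- resize_image(array(rep(m, 3), c(dim(m), 3)), H0, W0)[, , 1]
  up <- pmin(pmax(up, 0), 1)
  heat <- array(0, c(H0, W0, 3))
  heat[, , 1] <- up
  heat[, , 2] <- pmax(0, 1 - abs(2 * up - 1))
  heat[, , 3] <- 1 - up
  list(map = up, overlay = 0.5 * image + 0.5 * heat)
}
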