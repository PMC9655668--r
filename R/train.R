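# SGD training: linear-warmup learning rate, uniform anchor matching, focal
# classification loss on sigmoid(class) * sigmoid(objectness), GIoU box
# regression on positives. Loss and its gradient with respect to the head
# outputs are computed in R (the head maps are small); the C++ engine
# backpropagates them to every weight.

#' Training configuration
#'
#' Defaults follow the published recipe: SGD, mini-batch 4, initial learning
#' rate 0.12, 12 epochs, 1500 warmup iterations. Momentum 0.9 and weight
#' decay 1e-4 are conventional SGD settings, declared here and overridable.
#'
#' @param batch_size mini-batch size (default 4).
#' @param base_lr learning rate after warmup (default 0.12).
#' @param epochs training epochs (default 12).
#' @param warmup_iters linear warmup length in iterations (default 1500).
#' @param momentum,weight_decay SGD settings.
#' @param iterations optional explicit iteration count overriding
#'   `epochs * ceil(n / batch_size)` (handy for short smoke runs).
#' @param image_size training input side; defaults to the model's configured
#'   size.
#' @param flip_prob probability of each of the horizontal / vertical flips
#'   (applied independently, training only).
#' @param match_k positive anchors per ground truth (uniform matching).
#' @param clip_norm global gradient-norm clip (default 10; 0 disables).
#' @param box_weight weight of the box-regression loss relative to the
#'   classification loss (default 1).
#' @param seed RNG seed for shuffling, flips and any weight init.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 4, base_lr = 0.12, epochs = 12,
                         warmup_iters = 1500, momentum = 0.9,
                         weight_decay = 1e-4, iterations = NULL,
                         image_size = NULL, flip_prob = 0.5, match_k = 4,
                         clip_norm = 10, box_weight = 1, seed = 1L) {
  if (base_lr <= 0) stop("base_lr must be positive")
  if (warmup_iters < 0) stop("warmup_iters must be >= 0")
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 epochs = as.integer(epochs),
                 warmup_iters = as.integer(warmup_iters),
                 momentum = momentum, weight_decay = weight_decay,
                 iterations = if (is.null(iterations)) NULL else as.integer(iterations),
                 image_size = image_size, flip_prob = flip_prob,
                 match_k = as.integer(match_k), clip_norm = clip_norm,
                 box_weight = box_weight, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at an iteration
#'
#' Linear warmup from `base_lr / 1000` at iteration 0 to `base_lr` at
#' `warmup_iters`, constant afterwards (continuous at the boundary).
#'
#' @param iter iteration index (0-based).
#' @param cfg [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(iter, cfg) {
  if (iter >= cfg$warmup_iters || cfg$warmup_iters == 0) return(cfg$base_lr)
  f0 <- 1 / 1000
  cfg$base_lr * (f0 + (1 - f0) * iter / cfg$warmup_iters)
}

# ---- head layout helpers -------------------------------------------------
# engine head arrays are (N, C, G, G); anchors are ordered cell-major with
# the per-cell anchor index fastest, matching channel layout (k fastest
# within anchor for cls, coordinate fastest for box)

head_to_mat <- function(arr, n, inner) {
  d <- dim(arr)
  a <- arr[n, , , ]
  dim(a) <- c(inner, d[2] / inner, d[3], d[4])   # (inner, A, H, W)
  a <- aperm(a, c(1, 2, 4, 3))                   # (inner, A, W, H)
  t(matrix(a, nrow = inner))                     # (A*W*H, inner) anchor-major
}

mat_to_head <- function(m, inner, G) {
  A <- nrow(m) / (G * G)
  a <- array(t(m), c(inner, A, G, G))            # (inner, A, W, H)
  aperm(a, c(1, 2, 4, 3))                        # (inner, A, H, W) -> flatten
}

# ---- loss ----------------------------------------------------------------

# loss and d(loss)/d(head outputs) for one batch. Regression on positives
# combines GIoU with a delta-space smooth-L1 (Huber) term toward the encoded
# targets: it keeps the geometry well-conditioned when anchors start far from
# their boxes (where pure GIoU first inflates boxes and then stalls), damps
# to zero near the target, and GIoU shapes the final overlap.
detection_loss <- function(outputs, gt_list, anchors, K, A, match_k = 4,
                           l1_weight = 1, box_weight = 1) {
  cls <- outputs$cls; box <- outputs$box; obj <- outputs$obj
  N <- dim(cls)[1]; G <- dim(cls)[3]
  g_cls <- array(0, dim(cls)); g_box <- array(0, dim(box)); g_obj <- array(0, dim(obj))
  loss_cls <- 0; loss_box <- 0; n_pos_tot <- 0
  per_img <- vector("list", N)
  for (n in seq_len(N)) {
    cl <- head_to_mat(cls, n, K)          # (nA, K) logits
    bx <- head_to_mat(box, n, 4)
    ob <- head_to_mat(obj, n, 1)[, 1]
    gt <- gt_list[[n]]
    m <- uniform_match(gt$boxes, anchors, k = match_k)
    sc <- sigmoid(cl)
    so <- sigmoid(ob)
    p <- sc * so                           # (nA, K)
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    y <- matrix(0, nrow(cl), K)
    pos <- which(m$labels > 0)
    if (length(pos))
      y[cbind(pos, gt$class_idx[m$labels[pos]])] <- 1
    valid <- m$labels >= 0
    alpha <- 0.25; gamma <- 2
    fl <- ifelse(y > 0, -alpha * (1 - p)^gamma * log(p),
                 -(1 - alpha) * p^gamma * log(1 - p))
    dfl_dp <- ifelse(y > 0,
                     -alpha * (-gamma * (1 - p)^(gamma - 1) * log(p) +
                               (1 - p)^gamma / p),
                     -(1 - alpha) * (gamma * p^(gamma - 1) * log(1 - p) -
                                     p^gamma / (1 - p)))
    fl[!valid, ] <- 0
    dfl_dp[!valid, ] <- 0
    loss_cls <- loss_cls + sum(fl)
    dcl <- dfl_dp * so * sc * (1 - sc)
    dob <- rowSums(dfl_dp * sc) * so * (1 - so)
    db <- matrix(0, nrow(bx), 4)
    if (length(pos)) {
      ap <- anchors[pos, , drop = FALSE]
      dp <- bx[pos, , drop = FALSE]
      dec <- decode_boxes(ap, dp, saturate = TRUE)
      gtb <- gt$boxes[m$labels[pos], , drop = FALSE]
      gw <- getOption("encanet.giou_w", 1)
      loss_box <- loss_box + sum(1 - giou(dec, gtb))
      # gradient of -GIoU wrt the decoded (cx, cy, w, h), central differences,
      # then chain through the delta coding
      gdec <- matrix(0, length(pos), 4)
      cxywh <- cbind(dec[, 1] + dec[, 3] / 2, dec[, 2] + dec[, 4] / 2,
                     dec[, 3], dec[, 4])
      to_xywh <- function(cc) cbind(cc[, 1] - cc[, 3] / 2,
                                    cc[, 2] - cc[, 4] / 2, cc[, 3], cc[, 4])
      for (q in 1:4) {
        # relative step for the size coordinates so sub-pixel boxes keep a
        # well-conditioned difference quotient
        h <- if (q >= 3) pmax(0.01, 0.02 * cxywh[, q]) else rep(0.05, length(pos))
        cp <- cxywh; cp[, q] <- cp[, q] + h
        cm <- cxywh; cm[, q] <- cm[, q] - h
        if (q >= 3) cm[, q] <- pmax(cm[, q], 1e-3)
        gdec[, q] <- -(giou(to_xywh(cp), gtb) - giou(to_xywh(cm), gtb)) /
          (cp[, q] - cm[, q])
      }
      # chain through the saturating box coder (derivative never vanishes,
      # so overshooting deltas can always recover)
      lim <- delta_limits()
      db[pos, 1] <- gw * gdec[, 1] * ap$w * saturate_grad(dp[, 1], lim["xy"])
      db[pos, 2] <- gw * gdec[, 2] * ap$h * saturate_grad(dp[, 2], lim["xy"])
      db[pos, 3] <- gw * gdec[, 3] * dec[, 3] * saturate_grad(dp[, 3], lim["wh"])
      db[pos, 4] <- gw * gdec[, 4] * dec[, 4] * saturate_grad(dp[, 4], lim["wh"])
      db[pos, ] <- pmin(pmax(db[pos, ], -4), 4)
      if (l1_weight > 0) {
        tgt <- encode_boxes(ap, gtb)
        e <- dp - tgt
        hub <- ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
        loss_box <- loss_box + l1_weight * sum(hub)
        db[pos, ] <- db[pos, ] + l1_weight * pmin(pmax(e, -1), 1)
      }
    }
    n_pos_tot <- n_pos_tot + length(pos)
    per_img[[n]] <- list(dcl = dcl, dob = dob, db = db)
  }
  norm <- max(1, n_pos_tot)
  for (n in seq_len(N)) {
    g_cls[n, , , ] <- mat_to_head(per_img[[n]]$dcl / norm, K, G)
    g_box[n, , , ] <- mat_to_head(box_weight * per_img[[n]]$db / norm, 4, G)
    g_obj[n, , , ] <- mat_to_head(matrix(per_img[[n]]$dob / norm), 1, G)
  }
  list(loss_cls = loss_cls / norm, loss_box = loss_box / norm,
       total = (loss_cls + box_weight * loss_box) / norm, n_pos = n_pos_tot,
       grads = list(cls = g_cls, box = g_box, obj = g_obj))
}

# assemble a normalized (N, 3, S, S) input tensor from records
records_to_input <- function(recs) {
  S <- dim(recs[[1]]$image)[1]
  x <- array(0, c(length(recs), 3, S, S))
  for (n in seq_along(recs))
    x[n, , , ] <- aperm(normalize_image(recs[[n]]$image), c(3, 1, 2))
  x
}

#' Train a detector with SGD
#'
#' Runs `epochs * ceil(n / batch_size)` iterations (or `cfg$iterations`) of
#' SGD with momentum over the records: random flips, linear-warmup learning
#' rate, focal + GIoU losses with uniform anchor matching. Aborts with a
#' diagnostic naming the offending loss term if the loss becomes
#' non-finite.
#'
#' @param model an [encanet()] model.
#' @param records dataset records with in-memory images (e.g. from
#'   [generate_dataset()]).
#' @param cfg a [train_config()].
#' @param verbose print a progress line every 50 iterations.
#' @return list with the trained `model` and the per-iteration loss `log`
#'   (data.frame: iter, lr, loss_cls, loss_box, total).
#' @export
train_encanet <- function(model, records, cfg = train_config(),
                          verbose = FALSE) {
  if (length(records) == 0) stop("dataset is empty")
  S <- if (is.null(cfg$image_size)) model$config$image_size else as.integer(cfg$image_size)
  if (S %% model$config$stride != 0) stop("image_size must be divisible by stride")
  K <- model$config$num_classes; A <- model$config$anchors_per_cell
  cats <- attr(records, "categories")
  if (is.null(cats)) cats <- synthetic_categories()
  prep <- lapply(records, function(r) {
    if (is.null(r$image)) stop("records must carry in-memory images")
    r <- resize_with_boxes(r, S)
    r$class_idx <- match(r$categories, cats$name)
    r
  })
  anchors <- generate_anchors(A, model$config$stride, S)
  n <- length(prep)
  iters <- if (!is.null(cfg$iterations)) cfg$iterations
           else cfg$epochs * as.integer(ceiling(n / cfg$batch_size))
  rs <- rng_scope(cfg$seed)
  on.exit(rs(), add = TRUE)
  decay_mask <- vapply(model$net$params, function(p)
    grepl("\\.w$", p$name), TRUE)
  log <- data.frame(iter = integer(iters), lr = numeric(iters),
                    loss_cls = numeric(iters), loss_box = numeric(iters),
                    total = numeric(iters))
  if (iters == 0) return(list(model = model, log = log))
  stream <- integer(0)
  ctx <- eng_ctx(model$net$instrs, use_double = FALSE)
  eng_ctx_load_params(ctx, unname(model$params))
  out_ids <- as.integer(unlist(model$net$outputs))
  for (it in seq_len(iters)) {
    while (length(stream) < cfg$batch_size) stream <- c(stream, sample.int(n))
    take <- stream[seq_len(cfg$batch_size)]
    stream <- stream[-seq_len(cfg$batch_size)]
    batch <- lapply(prep[take], function(r) {
      if (runif(1) < cfg$flip_prob) r <- flip_record(r, "h")
      if (runif(1) < cfg$flip_prob) r <- flip_record(r, "v")
      r
    })
    x <- records_to_input(batch)
    fw <- eng_ctx_forward_res(ctx, unname(model$state), x, TRUE, out_ids)
    names(fw$values) <- names(model$net$outputs)
    names(fw$state) <- names(model$state)
    model$state <- fw$state
    gt_list <- lapply(batch, function(r)
      list(boxes = r$boxes, class_idx = r$class_idx))
    ls <- detection_loss(fw$values, gt_list, anchors, K, A, cfg$match_k,
                         box_weight = if (is.null(cfg$box_weight)) 1 else cfg$box_weight)
    if (!is.finite(ls$total)) {
      term <- if (!is.finite(ls$loss_cls)) "focal classification loss"
              else "GIoU regression loss"
      stop("non-finite loss at iteration ", it, ": ", term)
    }
    eng_ctx_backward_res(ctx, unname(ls$grads), out_ids)
    lr <- lr_at(it - 1, cfg)
    eng_ctx_sgd(ctx, lr, cfg$momentum, cfg$weight_decay, decay_mask,
                if (is.null(cfg$clip_norm)) 0 else cfg$clip_norm)
    log[it, ] <- list(it, lr, ls$loss_cls, ls$loss_box, ls$total)
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %d/%d lr %.4f loss %.4f (cls %.4f box %.4f)",
                      it, iters, lr, ls$total, ls$loss_cls, ls$loss_box))
    if (it %% 50 == 0) gc(verbose = FALSE)
  }
  model$params <- setNames(eng_ctx_params(ctx), names(model$params))
  eng_free(ctx)
  list(model = model, log = log)
}
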