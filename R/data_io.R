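# COCO-format dataset IO, geometric augmentation and the 7:2:1 split
# protocol. A dataset record is a list with fields image_id, file_name,
# width, height, boxes (n x 4 xywh matrix, 0-based half-open pixel
# coordinates), categories (character), category_ids (integer), and
# optionally image (H x W x 3 array in [0,1]).

#' Per-channel normalization constants
#'
#' Fixed RGB mean / standard deviation applied to images before the network
#' (the ImageNet statistics conventionally used with EfficientNet backbones).
#' @return list with `mean` and `sd` length-3 vectors.
#' @export
image_norm_constants <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

normalize_image <- function(img) {
  nc <- image_norm_constants()
  for (c in 1:3) img[, , c] <- (img[, , c] - nc$mean[c]) / nc$sd[c]
  img
}

new_record <- function(image_id, file_name, width, height, boxes, categories,
                       category_ids, image = NULL) {
  boxes <- matrix(as.numeric(boxes), ncol = 4,
                  dimnames = list(NULL, c("x", "y", "w", "h")))
  list(image_id = as.integer(image_id), file_name = file_name,
       width = as.integer(width), height = as.integer(height),
       boxes = boxes, categories = as.character(categories),
       category_ids = as.integer(category_ids), image = image)
}

#' Read a COCO-format annotation file
#'
#' Parses a COCO JSON (images / annotations / categories arrays) into one
#' record per image, with annotations joined by `image_id` and category ids
#' mapped to names. Dangling references raise descriptive errors.
#'
#' @param json_path path to the COCO JSON.
#' @param images_dir optional directory with the referenced image files.
#' @param load_images read the PNG images into the records.
#' @return list of dataset records, with the category table as attribute
#'   `categories`.
#' @export
read_coco <- function(json_path, images_dir = NULL, load_images = FALSE) {
  if (!file.exists(json_path)) stop("no such file: ", json_path)
  j <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  for (key in c("images", "annotations", "categories"))
    if (is.null(j[[key]])) stop("COCO JSON missing '", key, "' array")
  cat_ids <- vapply(j$categories, function(x) as.integer(x$id), 0L)
  cat_names <- vapply(j$categories, function(x) as.character(x$name), "")
  img_ids <- vapply(j$images, function(x) as.integer(x$id), 0L)
  if (anyDuplicated(img_ids)) stop("duplicate image id ", img_ids[duplicated(img_ids)][1])
  ann_by_img <- split(j$annotations,
                      vapply(j$annotations, function(a) as.integer(a$image_id), 0L))
  bad <- setdiff(as.integer(names(ann_by_img)), img_ids)
  if (length(bad))
    stop("annotation references unknown image_id ", bad[1])
  records <- lapply(j$images, function(im) {
    anns <- ann_by_img[[as.character(im$id)]]
    if (is.null(anns)) anns <- list()
    boxes <- if (length(anns))
      do.call(rbind, lapply(anns, function(a) as.numeric(a$bbox)))
    else matrix(numeric(0), 0, 4)
    cids <- vapply(anns, function(a) as.integer(a$category_id), 0L)
    miss <- setdiff(cids, cat_ids)
    if (length(miss)) stop("annotation references unknown category_id ", miss[1])
    img <- NULL
    if (load_images) {
      f <- file.path(if (is.null(images_dir)) dirname(json_path) else images_dir,
                     im$file_name)
      img <- png::readPNG(f)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      img <- img[, , 1:3, drop = FALSE]
    }
    new_record(im$id, im$file_name, im$width, im$height, boxes,
               cat_names[match(cids, cat_ids)], cids, img)
  })
  attr(records, "categories") <- data.frame(id = cat_ids, name = cat_names)
  records
}

#' Write records as a COCO-format annotation file
#'
#' @param records list of dataset records.
#' @param json_path output path.
#' @param categories optional data.frame with `id`, `name`; defaults to the
#'   records' `categories` attribute or the categories present.
#' @return the path, invisibly.
#' @export
write_coco <- function(records, json_path, categories = NULL) {
  if (is.null(categories)) categories <- attr(records, "categories")
  if (is.null(categories)) {
    nm <- sort(unique(unlist(lapply(records, `[[`, "categories"))))
    categories <- data.frame(id = seq_along(nm), name = nm)
  }
  images <- lapply(records, function(r)
    list(id = r$image_id, file_name = r$file_name,
         width = r$width, height = r$height))
  anns <- list()
  aid <- 0L
  for (r in records) {
    if (nrow(r$boxes) == 0) next
    cid <- categories$id[match(r$categories, categories$name)]
    for (i in seq_len(nrow(r$boxes))) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = r$image_id,
                          category_id = cid[i],
                          bbox = as.numeric(r$boxes[i, ]),
                          area = r$boxes[i, 3] * r$boxes[i, 4],
                          iscrowd = 0L)
    }
  }
  cats <- lapply(seq_len(nrow(categories)), function(i)
    list(id = categories$id[i], name = categories$name[i],
         supercategory = "cells"))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

# bilinear image resize through EBImage (which indexes x, y)
resize_image <- function(img, height, width) {
  t <- aperm(img, c(2, 1, 3))
  r <- EBImage::resize(t, w = width, h = height)
  aperm(as.array(r), c(2, 1, 3))
}

#' Resize a record (image and boxes) to a square target
#'
#' Anisotropic resize to `target x target`: box coordinates scale by
#' `target/width` horizontally and `target/height` vertically, mirroring the
#' 640x480 -> 416x416 protocol.
#'
#' @param record dataset record.
#' @param target output side length (default 416).
#' @return resized record.
#' @export
resize_with_boxes <- function(record, target = 416) {
  if (record$width <= 0 || record$height <= 0)
    stop("zero-sized image cannot be resized")
  sx <- target / record$width
  sy <- target / record$height
  b <- record$boxes
  if (nrow(b)) {
    b[, 1] <- b[, 1] * sx; b[, 3] <- b[, 3] * sx
    b[, 2] <- b[, 2] * sy; b[, 4] <- b[, 4] * sy
  }
  record$boxes <- b
  if (!is.null(record$image) && (sx != 1 || sy != 1))
    record$image <- resize_image(record$image, target, target)
  record$width <- as.integer(target)
  record$height <- as.integer(target)
  record
}

#' Mirror a record horizontally or vertically
#'
#' Boxes map as `x' = W - x - w` (horizontal) or `y' = H - y - h` (vertical);
#' category labels are untouched. A double flip is the identity.
#'
#' @param record dataset record.
#' @param axis `"h"` or `"v"`.
#' @return flipped record.
#' @export
flip_record <- function(record, axis = c("h", "v")) {
  axis <- match.arg(axis)
  b <- record$boxes
  if (nrow(b)) {
    if (axis == "h") b[, 1] <- record$width - b[, 1] - b[, 3]
    else b[, 2] <- record$height - b[, 2] - b[, 4]
    record$boxes <- b
  }
  if (!is.null(record$image)) {
    record$image <- if (axis == "h") record$image[, rev(seq_len(dim(record$image)[2])), , drop = FALSE]
                    else record$image[rev(seq_len(dim(record$image)[1])), , , drop = FALSE]
  }
  record
}

#' Deterministic 7:2:1 dataset split
#'
#' Shuffles by seed, then sizes the validation and test sets as floors of
#' their proportions, giving every remainder image to the training set; the
#' partition is exact and disjoint (364 images split 256 / 72 / 36).
#'
#' @param records list of dataset records.
#' @param ratios positive split weights, default `c(7, 2, 1)` for
#'   train/val/test.
#' @param seed shuffle seed.
#' @return list with `train`, `val`, `test` record lists.
#' @export
split_dataset <- function(records, ratios = c(7, 2, 1), seed = 1L) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  n <- length(records)
  if (n < length(ratios)) stop("fewer records than splits")
  rs <- rng_scope(seed)
  on.exit(rs(), add = TRUE)
  idx <- sample.int(n)
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  keep_attr <- function(x) { attr(x, "categories") <- attr(records, "categories"); x }
  list(train = keep_attr(records[idx[seq_len(n_train)]]),
       val = keep_attr(records[idx[n_train + seq_len(n_val)]]),
       test = keep_attr(records[idx[n_train + n_val + seq_len(n_test)]]))
}

#' Write detections as COCO results JSON
#'
#' Serializes a detections data.frame (as returned by [detect()]) in the
#' standard COCO results format: an array of objects with `image_id`,
#' `category_id`, `bbox` (xywh) and `score`.
#'
#' @param detections data.frame with `image_id`, `category_id`, `score` and
#'   `x`, `y`, `w`, `h` columns.
#' @param json_path output path.
#' @return the path, invisibly.
#' @export
write_coco_results <- function(detections, json_path) {
  res <- lapply(seq_len(nrow(detections)), function(i)
    list(image_id = detections$image_id[i],
         category_id = detections$category_id[i],
         bbox = as.numeric(detections[i, c("x", "y", "w", "h")]),
         score = detections$score[i]))
  jsonlite::write_json(res, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
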