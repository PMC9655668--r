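# Synthetic blood-smear scenes with COCO annotations. The generator mimics
# the class structure of blood-smear detection data: many medium, roughly
# round RBC-like cells, a few large two-tone WBC-like cells, and a few tiny
# platelet-like specks, on a pale background with additive Gaussian noise.
# Scenes are fully deterministic given (config, seed).

#' Synthetic scene configuration
#'
#' Defaults encode the intended class structure: RBC 10-40 per image with
#' radius 14-26 px, WBC 1-3 with radius 28-44 px, platelets 2-8 with radius
#' 4-9 px at image size 416. Ellipse axis ratio is capped at 1.4; WBCs are
#' rendered as two concentric ellipses (nucleus on cytoplasm) to give the
#' detector non-trivial texture.
#'
#' @param image_size side length in pixels (default 416).
#' @param rbc_count,wbc_count,platelet_count integer ranges `c(lo, hi)`.
#' @param rbc_radius,wbc_radius,platelet_radius radius ranges in px.
#' @param max_overlap maximum bounding-box IoU tolerated between same-class
#'   objects during rejection sampling (default 0.3).
#' @param noise_sd additive Gaussian pixel noise (default 0.02).
#' @param background RGB background tint.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_size = 416,
                         rbc_count = c(10, 40), wbc_count = c(1, 3),
                         platelet_count = c(2, 8),
                         rbc_radius = c(14, 26), wbc_radius = c(28, 44),
                         platelet_radius = c(4, 9),
                         max_overlap = 0.3, noise_sd = 0.02,
                         background = c(0.93, 0.91, 0.89)) {
  ranges <- list(rbc_count = rbc_count, wbc_count = wbc_count,
                 platelet_count = platelet_count, rbc_radius = rbc_radius,
                 wbc_radius = wbc_radius, platelet_radius = platelet_radius)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("empty range for ", nm)
  }
  if (max(wbc_radius) >= image_size / 2)
    stop("radii must be below image_size / 2")
  structure(c(ranges, list(image_size = as.integer(image_size),
                           max_overlap = max_overlap, noise_sd = noise_sd,
                           background = background)),
            class = "scene_config")
}

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

synthetic_categories <- function() {
  data.frame(id = 1:3, name = c("Platelets", "RBC", "WBC"))
}

# paint one soft-edged rotated ellipse into img; returns img
paint_ellipse <- function(img, cx, cy, a, b, theta, col, soft = 1.5) {
  S <- dim(img)[1]
  ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  xs <- max(1, floor(cx - ex - 2)):min(S, ceiling(cx + ex + 2))
  ys <- max(1, floor(cy - ey - 2)):min(S, ceiling(cy + ey + 2))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  q <- sqrt((xr / a)^2 + (yr / b)^2)
  alpha <- pmin(1, pmax(0, (1 - q) * min(a, b) / soft))
  for (c in 1:3)
    img[ys, xs, c] <- img[ys, xs, c] * (1 - alpha) + col[c] * alpha
  img
}

#' Generate one synthetic blood-smear scene
#'
#' Draws per-class object counts uniformly from their ranges, places rotated
#' soft-edged ellipses with rejection sampling against the same-class overlap
#' cap (an object is dropped, with a warning, after 100 failed placements),
#' adds Gaussian noise and returns the image together with tight bounding
#' boxes and class labels.
#'
#' @param cfg [scene_config()].
#' @param seed integer seed; identical `(cfg, seed)` give bit-identical
#'   output.
#' @param image_id id stored in the record (default 1).
#' @return list with `image` (H x W x 3 array in `[0, 1]`) and `record`
#'   (dataset record with boxes in COCO xywh).
#' @export
generate_scene <- function(cfg = scene_config(), seed = 1L, image_id = 1L) {
  rs <- rng_scope(seed)
  on.exit(rs(), add = TRUE)
  S <- cfg$image_size
  img <- array(rep(cfg$background, each = S * S), c(S, S, 3))
  classes <- list(
    RBC = list(count = cfg$rbc_count, radius = cfg$rbc_radius,
               col = c(0.86, 0.58, 0.56)),
    Platelets = list(count = cfg$platelet_count, radius = cfg$platelet_radius,
                     col = c(0.58, 0.42, 0.68)),
    WBC = list(count = cfg$wbc_count, radius = cfg$wbc_radius,
               col = c(0.78, 0.72, 0.88)))
  boxes <- matrix(numeric(0), 0, 4)
  labels <- character(0)
  for (cl in names(classes)) {
    sp <- classes[[cl]]
    n_obj <- sample(sp$count[1]:sp$count[2], 1)
    placed <- matrix(numeric(0), 0, 4)
    for (o in seq_len(n_obj)) {
      ok <- FALSE
      for (try in 1:100) {
        r <- runif(1, sp$radius[1], sp$radius[2])
        ratio <- runif(1, 1, 1.4)
        a <- r; b <- r / ratio
        theta <- runif(1, 0, pi)
        ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
        ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
        cx <- runif(1, ex + 1, S - ex - 1)
        cy <- runif(1, ey + 1, S - ey - 1)
        bb <- c(cx - ex, cy - ey, 2 * ex, 2 * ey)
        if (nrow(placed) == 0 ||
            all(box_iou(matrix(bb, 1), placed) <= cfg$max_overlap)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        warning("overlap constraint infeasible; scene emitted with fewer ",
                cl, " objects")
        next
      }
      jit <- rnorm(3, 0, 0.03)
      img <- paint_ellipse(img, cx, cy, a, b, theta, clamp01(sp$col + jit))
      if (cl == "WBC")  # nucleus on top of cytoplasm
        img <- paint_ellipse(img, cx, cy, 0.55 * a, 0.55 * b, theta,
                             clamp01(c(0.45, 0.32, 0.62) + jit))
      placed <- rbind(placed, bb)
      boxes <- rbind(boxes, bb)
      labels <- c(labels, cl)
    }
  }
  img <- clamp01(img + array(rnorm(S * S * 3, 0, cfg$noise_sd), c(S, S, 3)))
  cats <- synthetic_categories()
  rec <- new_record(image_id, sprintf("scene_%05d.png", image_id), S, S,
                    boxes, labels, cats$id[match(labels, cats$name)],
                    image = img)
  list(image = img, record = rec)
}

#' Generate a synthetic dataset with COCO annotations
#'
#' Generates `n_images` scenes with per-scene seeds `seed + index` (so a
#' dataset can be extended without reshuffling existing scenes). When
#' `out_dir` is given, PNG images and one COCO JSON (`annotations.json`)
#' indexing all of them are written; the output re-reads cleanly with
#' [read_coco()].
#'
#' @param cfg [scene_config()].
#' @param n_images number of scenes (>= 1).
#' @param out_dir optional output directory.
#' @param seed master seed.
#' @return list of dataset records (images held in memory), with the
#'   category table as attribute `categories`.
#' @export
generate_dataset <- function(cfg = scene_config(), n_images = 20,
                             out_dir = NULL, seed = 1L) {
  if (n_images < 1) stop("n_images must be >= 1")
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(cfg, seed = seed + i, image_id = i)
    records[[i]] <- sc$record
    if (!is.null(out_dir))
      png::writePNG(sc$image, file.path(out_dir, sc$record$file_name))
  }
  attr(records, "categories") <- synthetic_categories()
  if (!is.null(out_dir))
    write_coco(records, file.path(out_dir, "annotations.json"),
               synthetic_categories())
  records
}
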