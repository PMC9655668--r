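# Learning-rate schedule, COCO metrics (closed cases + independent numpy
# oracle), inference plumbing, attention maps and training-loop contracts.

test_that("warmup schedule is linear, anchored at base/1000, continuous at the boundary", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.00012)
  expect_equal(lr_at(1500, cfg), 0.12)
  expect_equal(lr_at(5000, cfg), 0.12)
  mid <- (lr_at(0, cfg) + lr_at(1500, cfg)) / 2
  expect_equal(lr_at(750, cfg), mid)
  expect_equal(lr_at(1499, cfg), 0.12 - (0.12 - 0.00012) / 1500,
               tolerance = 1e-10)
  expect_error(train_config(base_lr = 0), "positive")
})

test_that("coco_eval: perfect detections score 100, empty detections score 0", {
  gt <- data.frame(image_id = rep(1:2, each = 2), category_id = c(1, 2, 2, 3),
                   x = c(10, 50, 30, 70), y = c(10, 50, 30, 70),
                   w = c(20, 30, 25, 40), h = c(20, 30, 25, 40))
  dt <- cbind(gt, score = 1.0)
  m <- coco_eval(dt, gt)
  expect_equal(m$AP, 100)
  expect_equal(m$AP50, 100)
  m0 <- coco_eval(dt[0, ], gt)
  expect_equal(unlist(m0), c(AP = 0, AP50 = 0, AP75 = 0, APS = 0, APM = 0,
                             APL = 0))
})

test_that("coco_eval matches hand-built precision-recall interpolation", {
  # 1 GT, a perfect detection plus a lower-scored duplicate: the duplicate is
  # a false positive at recall 1, so the interpolated envelope stays at 1
  gt <- data.frame(image_id = 1L, category_id = 1L, x = 10, y = 10, w = 30, h = 30)
  dt <- data.frame(image_id = 1L, category_id = 1L, score = c(0.9, 0.8),
                   x = c(10, 10), y = c(10, 10), w = c(30, 30), h = c(30, 30))
  expect_equal(coco_eval(dt, gt)$AP50, 100)

  # 2 GT, one matched det + one far false positive: precision envelope is 1
  # up to recall 0.5 and 0 beyond -> AP50 = 51/101
  gt2 <- data.frame(image_id = 1L, category_id = 1L, x = c(10, 100),
                    y = c(10, 100), w = c(30, 30), h = c(30, 30))
  dt2 <- data.frame(image_id = 1L, category_id = 1L, score = c(0.9, 0.8),
                    x = c(10, 200), y = c(10, 200), w = c(30, 30), h = c(30, 30))
  expect_equal(coco_eval(dt2, gt2)$AP50, 100 * 51 / 101, tolerance = 1e-8)
})

test_that("coco_eval agrees with the independent numpy oracle to 1e-4", {
  set.seed(18)
  gt <- do.call(rbind, lapply(1:6, function(im) {
    n <- sample(2:6, 1)
    data.frame(image_id = im, category_id = sample(1:3, n, TRUE),
               x = runif(n, 0, 300), y = runif(n, 0, 300),
               w = runif(n, 10, 80), h = runif(n, 10, 80))
  }))
  # detections: jittered copies of most GT plus random noise boxes
  jit <- gt[runif(nrow(gt)) < 0.8, ]
  jit$x <- jit$x + rnorm(nrow(jit), 0, 4)
  jit$y <- jit$y + rnorm(nrow(jit), 0, 4)
  jit$w <- pmax(5, jit$w * runif(nrow(jit), 0.8, 1.2))
  jit$h <- pmax(5, jit$h * runif(nrow(jit), 0.8, 1.2))
  jit$score <- runif(nrow(jit), 0.5, 1)
  noise <- data.frame(image_id = sample(1:6, 30, TRUE),
                      category_id = sample(1:3, 30, TRUE),
                      x = runif(30, 0, 300), y = runif(30, 0, 300),
                      w = runif(30, 5, 60), h = runif(30, 5, 60),
                      score = runif(30, 0, 0.6))
  dt <- rbind(jit, noise)
  mine <- coco_eval(dt, gt)

  to_list <- function(df, score) {
    lapply(seq_len(nrow(df)), function(i) {
      o <- list(image_id = df$image_id[i], category_id = df$category_id[i],
                bbox = c(df$x[i], df$y[i], df$w[i], df$h[i]))
      if (score) o$score <- df$score[i]
      o
    })
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(gt = to_list(gt, FALSE), dt = to_list(dt, TRUE)),
                       fin, auto_unbox = TRUE, digits = NA)
  status <- system2("python",
                    c(test_path("oracle_coco_eval.py"), fin, fout))
  expect_equal(status, 0L)
  ref <- jsonlite::fromJSON(fout)
  for (k in names(mine))
    expect_equal(mine[[k]], ref[[k]], tolerance = 1e-4, label = k)
})

test_that("detect returns well-formed records in original image coordinates", {
  m <- encanet(detector_config("b0", "ecbam", image_size = 96), seed = 4)
  sc <- generate_scene(scene_config(), seed = 5)
  dt <- detect(m, sc$record, eval_size = 96)
  expect_true(all(c("image_id", "category_id", "category", "score",
                    "x", "y", "w", "h") %in% names(dt)))
  if (nrow(dt)) {
    expect_true(all(dt$score >= 0.05 & dt$score <= 1))
    expect_true(all(dt$x >= 0 & dt$y >= 0))
    expect_true(all(dt$x + dt$w <= 416 + 1e-6))
    expect_true(all(dt$w > 0 & dt$h > 0))
    expect_lte(nrow(dt), 100)
  }
  p <- predict(m, list(sc$record), eval_size = 96)
  expect_equal(p, dt)
})

test_that("attention maps normalize to [0,1], match image size, and zero out degenerate taps", {
  m <- encanet(detector_config("b0", "ecbam", image_size = 96), seed = 6)
  sc <- generate_scene(scene_config(), seed = 7)
  am <- attention_map(m, sc$record, "after_encoder", eval_size = 96)
  expect_equal(dim(am$map), c(416, 416))
  expect_true(all(am$map >= 0 & am$map <= 1))
  expect_equal(dim(am$overlay), c(416, 416, 3))
  # degenerate (constant) feature maps normalize to all zeros by rule
  expect_identical(encanet:::normalize_heatmap(matrix(3.2, 4, 4)),
                   matrix(0, 4, 4))
  expect_equal(range(encanet:::normalize_heatmap(matrix(rnorm(16), 4))),
               c(0, 1))
  flat <- array(0.5, c(64, 64, 3))
  expect_error(attention_map(m, flat, "nowhere"), "tap")
})

test_that("training-loop contracts: zero epochs is a no-op and the log has one row per iteration", {
  recs <- generate_dataset(scene_config(image_size = 96, rbc_count = c(2, 4),
                                        wbc_radius = c(18, 24)),
                           4, seed = 60)
  m <- encanet(detector_config("b0", "ecam", image_size = 96), seed = 7)
  tr0 <- train_encanet(m, recs, train_config(epochs = 0, image_size = 96))
  expect_identical(tr0$model$params, m$params)
  expect_equal(nrow(tr0$log), 0)

  tr <- train_encanet(m, recs, train_config(iterations = 5, batch_size = 2,
                                            base_lr = 0.005, warmup_iters = 50,
                                            image_size = 96, seed = 2))
  expect_equal(nrow(tr$log), 5)
  expect_true(all(is.finite(tr$log$total)))
  expect_equal(tr$log$lr, vapply(0:4, lr_at, 0,
                                 cfg = train_config(base_lr = 0.005,
                                                    warmup_iters = 50)))
  expect_error(train_encanet(m, list(), train_config()), "empty")
})
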