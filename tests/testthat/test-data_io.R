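# COCO IO, geometric transforms and the split protocol.

make_coco_file <- function(path) {
  j <- list(
    images = list(list(id = 1L, file_name = "a.png", width = 640L, height = 480L)),
    annotations = list(
      list(id = 1L, image_id = 1L, category_id = 2L,
           bbox = c(100, 240, 50, 40), area = 2000, iscrowd = 0L),
      list(id = 2L, image_id = 1L, category_id = 3L,
           bbox = c(10, 20, 80, 90), area = 7200, iscrowd = 0L)),
    categories = list(list(id = 1L, name = "Platelets"),
                      list(id = 2L, name = "RBC"),
                      list(id = 3L, name = "WBC")))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("read_coco joins annotations by image and maps category names", {
  f <- make_coco_file(tempfile(fileext = ".json"))
  recs <- read_coco(f)
  expect_length(recs, 1)
  expect_equal(nrow(recs[[1]]$boxes), 2)
  expect_equal(recs[[1]]$categories, c("RBC", "WBC"))
  expect_equal(unname(recs[[1]]$boxes[1, ]), c(100, 240, 50, 40))
  expect_equal(attr(recs, "categories")$name, c("Platelets", "RBC", "WBC"))
})

test_that("COCO write -> read is lossless for ids, boxes and categories", {
  f <- make_coco_file(tempfile(fileext = ".json"))
  recs <- read_coco(f)
  f2 <- tempfile(fileext = ".json")
  write_coco(recs, f2)
  recs2 <- read_coco(f2)
  expect_equal(recs2[[1]]$image_id, recs[[1]]$image_id)
  expect_equal(recs2[[1]]$boxes, recs[[1]]$boxes)
  expect_equal(recs2[[1]]$categories, recs[[1]]$categories)
  expect_equal(recs2[[1]]$category_ids, recs[[1]]$category_ids)
})

test_that("dangling references raise descriptive errors", {
  f <- tempfile(fileext = ".json")
  j <- list(images = list(list(id = 1L, file_name = "a.png",
                               width = 10L, height = 10L)),
            annotations = list(list(id = 1L, image_id = 99L, category_id = 1L,
                                    bbox = c(0, 0, 5, 5))),
            categories = list(list(id = 1L, name = "RBC")))
  jsonlite::write_json(j, f, auto_unbox = TRUE)
  expect_error(read_coco(f), "unknown image_id 99")
  j$annotations[[1]]$image_id <- 1L
  j$annotations[[1]]$category_id <- 7L
  jsonlite::write_json(j, f, auto_unbox = TRUE)
  expect_error(read_coco(f), "unknown category_id 7")
  j$categories <- NULL
  jsonlite::write_json(j, f, auto_unbox = TRUE)
  expect_error(read_coco(f), "missing 'categories'")
  expect_error(read_coco(tempfile()), "no such file")
})

test_that("anisotropic resize scales boxes by 416/W and 416/H", {
  rec <- encanet:::new_record(1L, "a.png", 640, 480,
                              matrix(c(100, 240, 50, 40), 1), "RBC", 2L)
  r <- resize_with_boxes(rec, 416)
  expect_equal(unname(r$boxes[1, 1]), 65)            # 100 * 416/640
  expect_equal(unname(r$boxes[1, 2]), 208)           # 240 * 416/480
  expect_equal(c(r$width, r$height), c(416L, 416L))

  sq <- encanet:::new_record(1L, "b.png", 416, 416,
                             matrix(c(5, 6, 7, 8), 1), "WBC", 3L)
  expect_equal(resize_with_boxes(sq, 416)$boxes, sq$boxes)
})

test_that("flips mirror boxes, preserve labels, and are involutions", {
  rec <- encanet:::new_record(1L, "a.png", 416, 416,
                              matrix(c(0, 0, 10, 10), 1), "RBC", 2L)
  h <- flip_record(rec, "h")
  expect_equal(unname(h$boxes[1, ]), c(406, 0, 10, 10))
  expect_equal(h$categories, "RBC")
  expect_equal(flip_record(h, "h")$boxes, rec$boxes)
  v <- flip_record(rec, "v")
  expect_equal(unname(v$boxes[1, ]), c(0, 406, 10, 10))
  expect_equal(flip_record(v, "v")$boxes, rec$boxes)
  # pixel flips agree with box flips
  sc <- generate_scene(scene_config(image_size = 64, rbc_count = c(2, 2),
                                    wbc_count = c(1, 1), wbc_radius = c(10, 12),
                                    platelet_count = c(1, 1)), seed = 1)
  fh <- flip_record(sc$record, "h")
  expect_equal(fh$image[, 1, ], sc$record$image[, 64, ])
})

test_that("the 7:2:1 split floors val/test and gives the remainder to train", {
  recs <- replicate(10, list(image_id = 1L), simplify = FALSE)
  s <- split_dataset(recs, seed = 1)
  expect_equal(lengths(list(s$train, s$val, s$test)), c(7L, 2L, 1L))

  recs364 <- replicate(364, list(image_id = 1L), simplify = FALSE)
  s364 <- split_dataset(recs364, seed = 1)
  expect_equal(length(s364$train), 256L)
  expect_equal(length(s364$val), 72L)
  expect_equal(length(s364$test), 36L)

  # deterministic, disjoint, exhaustive
  recs2 <- lapply(1:23, function(i) list(image_id = i))
  a <- split_dataset(recs2, seed = 9)
  b <- split_dataset(recs2, seed = 9)
  expect_identical(a, b)
  ids <- c(vapply(a$train, `[[`, 0L, "image_id"),
           vapply(a$val, `[[`, 0L, "image_id"),
           vapply(a$test, `[[`, 0L, "image_id"))
  expect_setequal(ids, 1:23)
  expect_equal(length(ids), 23L)
  expect_error(split_dataset(recs2[1:2]), "fewer records")
})

test_that("detections serialize to COCO results JSON and read back", {
  dt <- data.frame(image_id = c(1L, 2L), category_id = c(2L, 3L),
                   category = c("RBC", "WBC"), score = c(0.9, 0.4),
                   x = c(10, 20), y = c(30, 40), w = c(15, 25), h = c(18, 28))
  f <- tempfile(fileext = ".json")
  write_coco_results(dt, f)
  j <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(j, 2)
  expect_equal(j[[1]]$image_id, 1L)
  expect_equal(unlist(j[[2]]$bbox), c(20, 40, 25, 28))
  expect_equal(j[[1]]$score, 0.9)
})
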