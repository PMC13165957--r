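test_that("YOLO labels denormalize to pixel waypoints", {
  f <- write_tmp_labels(c("0 0.25 0.25 0.1 0.1", "1 0.75 0.75 0.1 0.1"))
  sc <- read_yolo_labels(f, 200, 100)
  expect_s3_class(sc, "rose_scene")
  expect_equal(sc$class, c("bloom", "bud"))
  expect_equal(sc$x, c(50, 150))
  expect_equal(sc$y, c(25, 75))
  expect_equal(sc$source_line, c(1L, 2L))

  f1 <- write_tmp_labels("0 0.5 0.5 0.1 0.1")
  sc1 <- read_yolo_labels(f1, 100, 100)
  expect_equal(nrow(sc1), 1L)
  expect_equal(c(sc1$x, sc1$y), c(50, 50))
})

test_that("empty and blank-line label files yield empty scenes with n preserved", {
  f <- write_tmp_labels(character(0))
  sc <- read_yolo_labels(f, 100, 100)
  expect_equal(nrow(sc), 0L)

  # blank lines skipped, source_line keeps the file's own numbering
  f2 <- write_tmp_labels(c("", "0 0.5 0.5 0.1 0.1", "   ", "1 0.2 0.2 0.1 0.1"))
  sc2 <- read_yolo_labels(f2, 100, 100)
  expect_equal(nrow(sc2), 2L)
  expect_equal(sc2$source_line, c(2L, 4L))
})

test_that("malformed label input fails with an informative error", {
  f <- write_tmp_labels(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5 0.1"))
  expect_error(read_yolo_labels(f, 100, 100), "Line 2")
  f2 <- write_tmp_labels("7 0.5 0.5 0.1 0.1")
  expect_error(read_yolo_labels(f2, 100, 100), "class id")
  f3 <- write_tmp_labels("0 1.5 0.5 0.1 0.1")
  expect_error(read_yolo_labels(f3, 100, 100), "\\[0, 1\\]")
  f4 <- write_tmp_labels("0 0.5 0.5 0.1 0.1")
  expect_error(read_yolo_labels(f4, -100, 100), "positive")
  expect_error(read_yolo_labels(tempfile(), 10, 10), "not found")
})

test_that("YOLO write/read round-trip reproduces the scene", {
  sc <- generate_scene(scene_spec(), seed = 11)
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(sc, f)
  back <- read_yolo_labels(f, 640, 640)
  expect_equal(back$class, sc$class)
  expect_equal(back$x, sc$x, tolerance = 1e-8)
  expect_equal(back$y, sc$y, tolerance = 1e-8)
  # second round trip is exact relative to the first (serialization fixpoint)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("JSON detections use box midpoints and keep duplicates", {
  f <- write_tmp_json(list(
    image_width = 100, image_height = 100,
    detections = list(
      list(label = "bloom", bbox = c(10, 10, 30, 50)),
      list(label = "bud", bbox = c(10, 10, 30, 50), score = 0.9),
      list(label = "bud", bbox = c(10, 10, 30, 50), score = 0.2)
    )
  ))
  sc <- read_json_detections(f)
  expect_equal(sc$x, rep(20, 3))
  expect_equal(sc$y, rep(30, 3))
  expect_equal(sum(sc$class == "bud"), 2L) # coincident duplicates retained
  expect_equal(sc$score, c(NA, 0.9, 0.2)) # carried through, unused

  f_empty <- write_tmp_json(list(image_width = 10, image_height = 10,
                                 detections = list()))
  expect_equal(nrow(read_json_detections(f_empty)), 0L)
})

test_that("JSON schema violations are rejected", {
  f <- write_tmp_json(list(detections = list()))
  expect_error(read_json_detections(f), "image_width")
  f2 <- write_tmp_json(list(image_width = 10, image_height = 10,
                            detections = list(list(label = "bud",
                                                   bbox = c(30, 10, 10, 50)))))
  expect_error(read_json_detections(f2), "bbox")
})

test_that("pixel-budget rescaling follows the square-root rule", {
  # under budget: untouched
  r <- rescale_for_processing(640, 640, 1e6)
  expect_equal(r$factor, 1)
  expect_equal(c(r$working_width, r$working_height), c(640, 640))

  # full-resolution capture (4160 x 3120 = 12,979,200 px) against a 1 MP budget
  r2 <- rescale_for_processing(4160, 3120, 1e6)
  expect_equal(r2$factor, sqrt(1e6 / (4160 * 3120)))
  expect_equal(r2$factor, 0.27757, tolerance = 1e-4)
  expect_lt(r2$working_width * r2$working_height, 1e6 * 1.01)

  expect_error(rescale_for_processing(0, 100, 1e6), "positive")
})

test_that("coordinate mapping round-trips and rescaling is idempotent", {
  r <- rescale_for_processing(4160, 3120, 2^20)
  pts <- data.frame(x = c(100, 4000), y = c(100, 3000))
  back <- scale_points(scale_points(pts, r, "working"), r, "original")
  expect_equal(back$x, pts$x, tolerance = 0.5)
  expect_equal(back$y, pts$y, tolerance = 0.5)

  r_again <- rescale_for_processing(r$working_width, r$working_height, 2^20)
  expect_equal(r_again$factor, 1)
})

test_that("Lanczos resampling preserves constants and dimensions", {
  img <- matrix(0.5, 40, 60)
  out <- resize_image_lanczos(img, 0.5)
  expect_equal(dim(out), c(20, 30))
  expect_equal(max(abs(out - 0.5)), 0, tolerance = 1e-10)

  arr <- array(runif(40 * 60 * 3), c(40, 60, 3))
  out3 <- resize_image_lanczos(arr, 0.25)
  expect_equal(dim(out3), c(10, 15, 3))
  # downsampling a smooth gradient keeps its range approximately
  grad <- outer(seq(0, 1, length.out = 50), rep(1, 50))
  g <- resize_image_lanczos(grad, 0.4)
  expect_lt(max(g), 1.1)
  expect_gt(min(g), -0.1)
  expect_error(resize_image_lanczos(img, 0), "positive")
})
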