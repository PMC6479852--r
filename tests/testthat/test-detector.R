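test_that("resize_for_detection reaches the working frame with scale factors", {
  img <- array(runif(60 * 90 * 3), dim = c(60, 90, 3))
  rs <- resize_for_detection(img, c(300L, 400L))
  expect_equal(dim(rs$image), c(300, 400, 3))
  expect_equal(unname(rs$scale), c(60 / 300, 90 / 400))

  already <- array(runif(300 * 400 * 3), dim = c(300, 400, 3))
  rs2 <- resize_for_detection(already)
  expect_identical(rs2$image, already)
  expect_equal(unname(rs2$scale), c(1, 1))
  expect_error(resize_for_detection(array(0, dim = c(0, 4, 3))), "empty")
})

test_that("boxes map back to original coordinates through the scale factors", {
  ## full working frame maps to the full original frame
  b <- bbox(0, 0, 400, 300)
  orig <- map_box(b, c(sy = 3456 / 300, sx = 5184 / 400))
  expect_equal(unclass(orig),
               c(x_min = 0, y_min = 0, x_max = 5184, y_max = 3456),
               ignore_attr = TRUE)
  ## round trip
  b2 <- bbox(37, 20, 120, 95)
  fwd <- map_box(b2, c(sy = 4, sx = 8))
  back <- map_box(fwd, c(sy = 1 / 4, sx = 1 / 8))
  expect_equal(unclass(back), unclass(b2))
})

test_that("proposal window sizes cover the configured stump size range", {
  cfg <- detector_config()
  ws <- window_sizes(cfg)
  expect_true(min(ws) <= cfg$window_range[1])
  expect_true(max(ws) >= cfg$window_range[2] / cfg$scale_step)
  expect_true(all(diff(ws) > 0))
})

test_that("NMS keeps separated boxes, drops overlapping ones, idempotent", {
  d <- data.frame(x_min = c(10, 12, 200), y_min = c(10, 12, 200),
                  x_max = c(60, 62, 260), y_max = c(60, 62, 260),
                  score = c(0.9, 0.8, 0.7))
  kept <- nms_detections(d, sq_threshold = 0.3)
  expect_equal(nrow(kept), 2L)                 # near-duplicate suppressed
  expect_equal(kept$score, c(0.9, 0.7))
  expect_identical(nms_detections(kept, 0.3), kept)   # idempotence

  disjoint <- d[c(1, 3), ]
  expect_equal(nrow(nms_detections(disjoint, 0.3)), 2L)
  expect_equal(nrow(nms_detections(d[0, ], 0.3)), 0L)
})

test_that("a trained detector emits sorted, in-bounds detections", {
  m <- tiny_detector()
  sc <- tiny_scenes()[[1]]
  d <- detect(m, sc$image)
  expect_s3_class(d, "data.frame")
  if (nrow(d) > 1) expect_true(all(diff(d$score) <= 0))
  expect_true(all(d$score >= m$config$score_threshold))
  expect_true(all(d$x_min >= 0 & d$y_min >= 0))
  expect_true(all(d$x_max <= 400 & d$y_max <= 300))
  expect_error(detect(list(), sc$image), "stump_detector")
})

test_that("fully-convolutional window scoring equals naive patch scoring", {
  m <- tiny_detector()
  sc <- tiny_scenes()[[2]]
  side <- 96L
  lev <- score_level(m, sc$image, side)
  ps <- m$config$patch_size
  f <- ps / side
  h <- max(ps, round(300 * f)); w <- max(ps, round(400 * f))
  im <- resize_image(sc$image, h, w)
  set.seed(1)
  for (i in sample(nrow(lev), 8)) {
    y <- round(lev$y_min[i] * h / 300) + 1L
    x <- round(lev$x_min[i] * w / 400) + 1L
    X <- array(im[y:(y + ps - 1L), x:(x + ps - 1L), ], dim = c(ps, ps, 3, 1))
    expect_equal(lev$score[i], nn_predict(m$net, X)[1, 1], tolerance = 1e-10)
  }
})

test_that("detector training is reproducible for a fixed seed", {
  scenes <- tiny_scenes()[1:3]
  sched <- list(nn_sched_step(2e-2, 2, 16L), nn_sched_step(2e-3, 1, 16L))
  cfg <- detector_config(train_schedule = sched)
  m1 <- train_detector(scenes, cfg, seed = 5L)
  m2 <- train_detector(scenes, cfg, seed = 5L)
  d1 <- detect(m1, scenes[[1]]$image)
  d2 <- detect(m2, scenes[[1]]$image)
  expect_identical(d1, d2)
})

test_that("training rejects degenerate inputs", {
  expect_error(train_detector(list()), "empty")
  blank <- render_scene(scene_params(n_stumps = 0, seed = 1))
  expect_error(train_detector(list(blank)), "no stump")
})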