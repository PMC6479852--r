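test_that("severity class boundaries follow the grading rule", {
  expect_equal(as.character(class_from_ratio(0)), "NO_ROT")
  expect_equal(as.character(class_from_ratio(1e-6)), "ROT_LT_50")
  expect_equal(as.character(class_from_ratio(0.49)), "ROT_LT_50")
  expect_equal(as.character(class_from_ratio(0.5)), "ROT_GE_50")
  expect_equal(as.character(class_from_ratio(1)), "ROT_GE_50")
  expect_error(class_from_ratio(-0.1), "\\[0, 1\\]")
  expect_error(class_from_ratio(1.1), "\\[0, 1\\]")
  expect_identical(levels(class_from_ratio(0.2)), rot_class_levels(3))
})

test_that("rbr_ratio counts pixels and enforces the subset invariant", {
  stump <- matrix(FALSE, 20, 20); stump[1:10, 1:20] <- TRUE   # 200 px
  rot <- matrix(FALSE, 20, 20);   rot[1:5, 1:10] <- TRUE      # 50 px
  expect_equal(rbr_ratio(rot, stump), 0.25)
  expect_equal(rbr_ratio(stump, stump), 1)
  expect_equal(rbr_ratio(matrix(FALSE, 20, 20), stump), 0)
  expect_error(rbr_ratio(rot, matrix(FALSE, 20, 20)), "empty")
  bad <- rot; bad[15, 15] <- TRUE
  expect_error(rbr_ratio(bad, stump), "outside")
})

test_that("scene parameters are validated", {
  expect_error(scene_params(target_rbr_ratio = 1.2), "\\[0, 1\\]")
  expect_error(scene_params(occlusion_fraction = 0.5), "\\[0, 0.4\\]")
  expect_error(scene_params(stump_radius_range = c(0.3, 0.2)), "range")
  expect_error(scene_params(lighting_gain = c(-1, 1)), "positive")
  expect_error(scene_params(n_stumps = 0, target_rbr_ratio = 0.3),
               "unreachable")
})

test_that("rendering is deterministic and hits the target rot ratio", {
  p <- easy_params(target_rbr_ratio = 0.7, seed = 11L)
  sc1 <- render_scene(p)
  sc2 <- render_scene(p)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$stump_mask, sc2$stump_mask)
  for (target in seq(0, 0.9, by = 0.1)) {
    sc <- render_scene(easy_params(target_rbr_ratio = target, seed = 42L))
    expect_lt(abs(sc$rbr_ratio - target), 0.02)
  }
})

test_that("generated scenes satisfy the mask, bbox and class invariants", {
  scenes <- c(tiny_scenes(),
              generate_scene_set(c(2, 2, 2), scene_params(), seed = 77L))
  for (sc in scenes) {
    for (st in sc$stumps) {
      expect_false(any(st$rot_mask & !st$stump_mask))
      expect_equal(unclass(st$bbox), unclass(bbox_from_mask(st$stump_mask)))
      expect_equal(st$rbr_ratio, rbr_ratio(st$rot_mask, st$stump_mask))
      expect_identical(st$rot_class, class_from_ratio(st$rbr_ratio))
    }
    expect_true(all(sc$image >= 0 & sc$image <= 1))
    ## 8-bit quantized pixels survive a PNG round trip exactly
    expect_equal(sc$image, round(sc$image * 255) / 255)
  }
})

test_that("multi-stump scenes carry disjoint per-stump ground truth", {
  sc <- render_scene(scene_params(n_stumps = 3, seed = 9L,
                                  stump_radius_range = c(0.08, 0.15)))
  expect_gt(length(sc$stumps), 1L)
  all_masks <- Reduce(`+`, lapply(sc$stumps, `[[`, "stump_mask"))
  expect_true(all(all_masks <= 1))     # no overlap between stumps
})

test_that("blank scenes have no stump and allow zero target only", {
  sc <- render_scene(scene_params(n_stumps = 0, seed = 3L))
  expect_length(sc$stumps, 0)
})

test_that("class_mix_counts reproduces the reference dataset proportions", {
  expect_equal(unname(class_mix_counts(1000)), c(502L, 197L, 301L))
  expect_equal(unname(class_mix_counts(100)), c(50L, 20L, 30L))
  expect_equal(sum(class_mix_counts(37)), 37L)
  expect_equal(unname(class_mix_counts(10, c(5, 2, 3))), c(5L, 2L, 3L))
})

test_that("generate_dataset writes a deterministic, loadable dataset", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p <- scene_params(image_height = 120, image_width = 160)
  df1 <- generate_dataset(c(2, 1, 1), p, seed = 5L, out_dir = d1)
  df2 <- generate_dataset(c(2, 1, 1), p, seed = 5L, out_dir = d2)
  expect_equal(nrow(df1), 4L)
  expect_equal(as.integer(table(df1$rot_class)), c(2L, 1L, 1L))
  ## byte-identical outputs for the same seed
  expect_identical(readBin(file.path(d1, "annotations.json"), "raw", 1e6),
                   readBin(file.path(d2, "annotations.json"), "raw", 1e6))
  img1 <- list.files(file.path(d1, "images"), full.names = TRUE)[1]
  img2 <- list.files(file.path(d2, "images"), full.names = TRUE)[1]
  expect_identical(readBin(img1, "raw", 1e6), readBin(img2, "raw", 1e6))

  idx <- read_annotations(d1)
  expect_identical(as.character(idx$rot_class), df1$rot_class)
  sc <- load_scene(d1, 1L)
  expect_s3_class(sc, "labeled_scene")
  expect_equal(sc$rbr_ratio, df1$rbr_ratio[1], tolerance = 1e-9)
  expect_equal(unclass(sc$bbox), unclass(bbox_from_mask(sc$stump_mask)))
})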