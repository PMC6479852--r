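det_df <- function(...) {
  v <- c(...)
  m <- matrix(if (is.null(v)) numeric(0) else v, ncol = 5, byrow = TRUE)
  data.frame(x_min = m[, 1], y_min = m[, 2], x_max = m[, 3], y_max = m[, 4],
             score = m[, 5])
}

test_that("detection matching follows the one-to-one sq protocol", {
  lab <- list(bbox(10, 10, 60, 60))

  ## one detection above threshold
  ev <- match_detections(det_df(12, 12, 62, 62, 0.9), lab)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(1L, 0L, 0L))
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)

  ## no detections
  ev0 <- match_detections(det_df(), lab)
  expect_equal(c(ev0$tp, ev0$fp, ev0$fn), c(0L, 0L, 1L))

  ## two good detections, one label: one-to-one leaves one FP
  ev2 <- match_detections(det_df(10, 10, 60, 60, 0.9,
                                 12, 12, 62, 62, 0.8), lab)
  expect_equal(c(ev2$tp, ev2$fp, ev2$fn), c(1L, 1L, 0L))

  ## below-threshold overlap is FP + FN
  ev3 <- match_detections(det_df(40, 40, 90, 90, 0.9), lab)
  expect_equal(c(ev3$tp, ev3$fp, ev3$fn), c(0L, 1L, 1L))

  ## boundary comparison is configurable
  half <- det_df(10, 35, 60, 85, 0.9)            # sq exactly 0.5
  expect_equal(match_detections(half, lab, 0.5, ">=")$tp, 1L)
  expect_equal(match_detections(half, lab, 0.5, ">")$tp, 0L)
})

test_that("matching conserves counts over random configurations", {
  set.seed(61)
  for (i in 1:50) {
    nl <- sample(0:4, 1); nd <- sample(0:6, 1)
    labs <- replicate(nl, random_bbox(200, 200), simplify = FALSE)
    dets <- if (nd > 0) {
      do.call(rbind, lapply(seq_len(nd), function(j) {
        b <- random_bbox(200, 200)
        data.frame(x_min = b[["x_min"]], y_min = b[["y_min"]],
                   x_max = b[["x_max"]], y_max = b[["y_max"]],
                   score = runif(1))
      }))
    } else det_df()
    ev <- match_detections(dets, labs)
    expect_equal(ev$tp + ev$fn, nl)
    expect_equal(ev$tp + ev$fp, nd)
    expect_true(all(table(ev$matches$label) <= 1))
    expect_true(all(table(ev$matches$detection) <= 1))
  }
})

test_that("headline precision/recall render as in the reference protocol", {
  ## TP 162, FP 9, FN 39
  expect_equal(render_percent_int(162 / 171, "round"), "95%")
  expect_equal(render_percent_int(162 / 201, "truncate"), "80%")
})

test_that("confusion matrices count true-by-predicted", {
  lv2 <- rot_class_levels(2)
  cm <- confusion_matrix(c("NO_ROT", "NO_ROT", "ROT"),
                         c("NO_ROT", "ROT", "ROT"), lv2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(true = lv2,
                                                   predicted = lv2)))
  ## perfect predictions give a diagonal matrix
  p <- rep(rot_class_levels(3), times = c(3, 2, 4))
  cmp <- confusion_matrix(p, p)
  expect_equal(unname(diag(unclass(cmp))), c(3L, 2L, 4L))
  expect_equal(sum(cmp) - sum(diag(unclass(cmp))), 0L)
  ## empty input -> all zeros
  cm0 <- confusion_matrix(character(0), character(0), lv2)
  expect_true(all(cm0 == 0L))
  expect_error(confusion_matrix("NO_ROT", "WHAT", lv2), "unknown")
  expect_error(confusion_matrix(c("NO_ROT", "ROT"), "ROT", lv2), "equal length")
})

test_that("per-class accuracies truncate to one decimal as printed", {
  a <- per_class_accuracy(as_confusion_matrix(rbind(c(94, 9), c(9, 89)),
                                              rot_class_levels(2)))
  expect_equal(a$rendered, c("91.2%", "90.8%"))
  expect_equal(a$accuracy, c(94 / 103, 89 / 98))

  b <- per_class_accuracy(as_confusion_matrix(
    rbind(c(84, 12, 7), c(6, 51, 4), c(3, 5, 29)), rot_class_levels(3)))
  expect_equal(b$rendered, c("81.5%", "83.6%", "78.3%"))

  ## truncation, not rounding: 61/73 = 83.56% -> "83.5%"
  c_ <- per_class_accuracy(as_confusion_matrix(rbind(c(61, 12), c(20, 69)),
                                               rot_class_levels(2)))
  expect_equal(c_$rendered[1], "83.5%")

  ident <- per_class_accuracy(as_confusion_matrix(diag(3L) * 5L,
                                                  rot_class_levels(3)))
  expect_equal(ident$rendered, rep("100.0%", 3))

  degen <- as_confusion_matrix(rbind(c(2, 0), c(0, 0)), rot_class_levels(2))
  expect_error(per_class_accuracy(degen), "undefined")
})

test_that("bundled reference tables recompute from their counts", {
  rt <- reproduce_reference_tables()
  acc <- rt$accuracies
  expect_equal(nrow(acc), 30L)        # 6 two-class + 9 + 6 + 9 three-class rows
  expect_equal(length(unique(acc$table)), 12L)

  ## two table cells in the source carry accuracies inconsistent with their
  ## own printed counts (65/103 prints 63.0, 70/99 prints 71.4); all other
  ## 28 recompute exactly under the truncation convention
  inconsistent <- acc[!acc$consistent, ]
  expect_equal(nrow(inconsistent), 2L)
  expect_setequal(inconsistent$table, c("1a", "1b"))
  expect_setequal(inconsistent$rendered, c("63.1%", "70.7%"))
  expect_true(all(acc$consistent[!acc$table %in% c("1a", "1b")]))

  expect_equal(rt$detection$precision_rendered, "95%")
  expect_equal(rt$detection$recall_rendered, "80%")
  expect_equal(rt$detection$precision, 162 / 171)
  expect_equal(rt$detection$recall, 162 / 201)
})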