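test_that("balance_classes draws exact per-class counts deterministically", {
  labels <- factor(rep(c("NO_ROT", "ROT_LT_50", "ROT_GE_50"),
                       times = c(40, 16, 24)))
  idx <- balance_classes(labels, per_class = 16, seed = 3)
  expect_length(idx, 48L)
  expect_equal(as.integer(table(labels[idx])), c(16L, 16L, 16L))
  expect_false(any(duplicated(idx)))                    # without replacement
  expect_identical(idx, balance_classes(labels, 16, seed = 3))
  expect_false(identical(idx, balance_classes(labels, 16, seed = 4)))

  ## NULL uses the smallest class; balanced input is kept whole
  idx_min <- balance_classes(labels, NULL, seed = 1)
  expect_equal(as.integer(table(labels[idx_min])), c(16L, 16L, 16L))
  expect_error(balance_classes(labels, per_class = 17), "fewer")
})

test_that("2-class mode collapses the severity labels", {
  y <- factor(c("NO_ROT", "ROT_LT_50", "ROT_GE_50"),
              levels = rot_class_levels(3))
  expect_equal(as.character(project_labels(y, 2)), c("NO_ROT", "ROT", "ROT"))
  expect_identical(levels(project_labels(y, 2)), rot_class_levels(2))
  expect_identical(project_labels(y, 3), y)
})

test_that("classifier specs validate their settings", {
  expect_error(classifier_spec(n_classes = 4), "2 or 3")
  expect_error(classifier_spec(balance_per_class = 0), ">= 1")
  expect_error(classifier_spec(approach = "XX"))
  s <- classifier_spec("BS", 2, balance_per_class = NULL, bof_k = 30)
  expect_equal(s$approach, "BS")
  expect_equal(s$n_classes, 2L)
})

## One small balanced crop set shared by the approach tests.
clf_data <- function() fixture("clf_data", function() {
  pars <- easy_params(image_height = 160, image_width = 214,
                      stump_radius_range = c(0.22, 0.38))
  crops_from_scenes(generate_scene_set(c(8, 8, 8), pars, seed = 515L))
})

test_that("BS trains a vocabulary + SVM and separates the training set", {
  cd <- clf_data()
  spec <- classifier_spec("BS", n_classes = 2, balance_per_class = NULL,
                          bof_k = 25)
  m <- train_rot_classifier(spec, cd$crops, cd$labels, seed = 2)
  expect_s3_class(m, "rot_classifier")
  expect_equal(m$vocab$k, 25L)
  pred <- predict(m, cd$crops)
  expect_identical(levels(pred), rot_class_levels(2))
  ## the SVM separates its own (balanced) training crops
  y2 <- project_labels(cd$labels, 2)
  keep <- balance_classes(y2, NULL, seed = stumpRBR:::derive_seeds(2, 4)[1])
  expect_gt(mean(predict(m, cd$crops[keep]) == y2[keep]), 0.7)
})

test_that("VS trains an SVM on penultimate CNN features", {
  cd <- clf_data()
  spec <- classifier_spec("VS", n_classes = 3, balance_per_class = NULL)
  m <- train_rot_classifier(spec, cd$crops, cd$labels, seed = 2,
                            backbone = tiny_backbone())
  pred <- predict(m, cd$crops)
  expect_identical(levels(pred), rot_class_levels(3))
  expect_gt(mean(pred == cd$labels), 0.7)      # mostly separable in training
})

test_that("VF attaches a fresh head of the requested width and fine-tunes", {
  cd <- clf_data()
  ft <- list(batch_size = 16L, initial_lr = 2e-3, max_epochs = 6L,
             lr_boost_new_layers = 10)
  for (nc in c(2L, 3L)) {
    spec <- classifier_spec("VF", n_classes = nc, balance_per_class = NULL,
                            finetune = ft)
    m <- train_rot_classifier(spec, cd$crops, cd$labels, seed = 2,
                              backbone = tiny_backbone())
    layers <- m$net$layers
    nl <- length(layers)
    expect_equal(nrow(layers[[nl]]$W), nc)        # final FC width = classes
    expect_equal(nrow(layers[[nl - 2L]]$W), 64L)  # FC-64 head
    expect_equal(layers[[nl]]$lr_mult, 10)        # boosted new layers
    expect_equal(layers[[1L]]$lr_mult, 1)         # original layers at base
    pred <- predict(m, cd$crops)
    expect_identical(levels(pred), rot_class_levels(nc))
  }
})

test_that("predictions are deterministic and consistent for identical crops", {
  cd <- clf_data()
  spec <- classifier_spec("BS", n_classes = 2, balance_per_class = NULL,
                          bof_k = 25)
  m <- train_rot_classifier(spec, cd$crops, cd$labels, seed = 2)
  one <- cd$crops[[1]]
  p <- predict(m, list(one, one))
  expect_equal(p[1], p[2])
  expect_identical(predict(m, one), predict(m, one))
})

test_that("training validates inputs", {
  cd <- clf_data()
  spec <- classifier_spec("BS", balance_per_class = NULL)
  expect_error(train_rot_classifier(spec, list(), factor(character(0))),
               "no training crops")
  expect_error(train_rot_classifier(spec, cd$crops[1:2],
                                    cd$labels[c(1, 1)]),
               "class has no training crops")
})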