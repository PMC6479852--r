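## Shared fixtures, built lazily once per test run.

## White-box access to package internals exercised by the engine tests.
nn_conv <- stumpRBR:::nn_conv
nn_relu <- stumpRBR:::nn_relu
nn_pool <- stumpRBR:::nn_pool
nn_flatten <- stumpRBR:::nn_flatten
nn_fc <- stumpRBR:::nn_fc
nn_init <- stumpRBR:::nn_init
nn_forward <- stumpRBR:::nn_forward
nn_backward <- stumpRBR:::nn_backward
nn_predict <- stumpRBR:::nn_predict
nn_train <- stumpRBR:::nn_train
softmax_cols <- stumpRBR:::softmax_cols
conv_forward <- stumpRBR:::conv_forward
pool_forward <- stumpRBR:::pool_forward
pool_backward <- stumpRBR:::pool_backward
score_level <- stumpRBR:::score_level
window_sizes <- stumpRBR:::window_sizes
project_labels <- stumpRBR:::project_labels
as_confusion_matrix <- stumpRBR:::as_confusion_matrix
render_percent_int <- stumpRBR:::render_percent_int
config_hash <- stumpRBR:::config_hash

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

## Easy acquisition conditions: no occlusion, flat lighting, no shadow.
easy_params <- function(...) {
  scene_params(occlusion_fraction = 0, lighting_gain = c(1, 1),
               shadow = FALSE, ...)
}

## A handful of labeled scenes, one per call site need.
tiny_scenes <- function() fixture("tiny_scenes", function()
  generate_scene_set(c(3, 2, 2), easy_params(), seed = 421L))

## A stump crop with rot, reused by feature tests.
rot_crop <- function() fixture("rot_crop", function() {
  sc <- render_scene(easy_params(target_rbr_ratio = 0.4, seed = 5L))
  b <- sc$bbox
  sc$image[(b[["y_min"]] + 1):b[["y_max"]],
           (b[["x_min"]] + 1):b[["x_max"]], , drop = FALSE]
})

## Short-schedule detector for structural tests (not a quality benchmark).
tiny_detector <- function() fixture("tiny_detector", function() {
  sched <- list(nn_sched_step(2e-2, 4, 16L), nn_sched_step(2e-3, 2, 16L))
  train_detector(tiny_scenes(), detector_config(train_schedule = sched),
                 seed = 99L)
})

## Short-schedule backbone for classifier tests.
tiny_backbone <- function() fixture("tiny_backbone", function()
  train_backbone(n_aux_per_class = 8L,
                 schedule = list(nn_sched_step(2e-2, 6, 16L)), seed = 31L))

## Crops + labels from a small balanced scene set.
crops_from_scenes <- function(scenes) {
  crops <- list(); labels <- character(0)
  for (sc in scenes) for (st in sc$stumps) {
    b <- st$bbox
    crops[[length(crops) + 1L]] <-
      sc$image[(b[["y_min"]] + 1):b[["y_max"]],
               (b[["x_min"]] + 1):b[["x_max"]], , drop = FALSE]
    labels <- c(labels, as.character(st$rot_class))
  }
  list(crops = crops, labels = factor(labels, levels = rot_class_levels(3)))
}

## Random valid bbox within a frame.
random_bbox <- function(W = 100, H = 100) {
  x <- sort(sample.int(W + 1, 2) - 1)
  y <- sort(sample.int(H + 1, 2) - 1)
  if (x[1] == x[2]) x[2] <- x[2] + 1
  if (y[1] == y[2]) y[2] <- y[2] + 1
  bbox(x[1], y[1], x[2], y[2])
}

## Pixel-counting oracle for sq on rasterized boxes.
sq_oracle_boxes <- function(a, b, W = 120, H = 120) {
  rasterize <- function(bb) {
    m <- matrix(FALSE, H, W)
    m[(bb[["y_min"]] + 1):bb[["y_max"]], (bb[["x_min"]] + 1):bb[["x_max"]]] <- TRUE
    m
  }
  S <- rasterize(a); L <- rasterize(b)
  O <- sum(S & L)
  (O / sum(L) + O / sum(S)) / 2
}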