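## Two-stage stump detector: class-agnostic multi-scale sliding-window
## proposals over the 300 x 400 working frame, each proposal scored by a
## small patch CNN (two 3x3x32 conv layers + ReLUs, one 2x2 max pool,
## FC-64 -> ReLU -> FC-2 -> softmax) on its 32 x 32 resampling. Proposals are
## generated on an image pyramid so every window is a plain 32 x 32 slice.

#' Four-step detector training schedule
#'
#' Both constructors return a list of four training steps (SGD with momentum
#' throughout, learning rate lowered 10x in the two fine-tuning steps, final
#' step shortened). `fullscale_train_schedule()` carries the configuration
#' used when training on full-resolution photographic datasets (mini-batch 1,
#' rates 1e-5 / 1e-6); `default_train_schedule()` keeps the same structure
#' but uses mini-batch 16 and rates suited to training the small patch CNN
#' from scratch on desk-scale synthetic scenes.
#'
#' @return list of four steps, each with `lr`, `epochs`, `batch`.
#' @export
default_train_schedule <- function() {
  list(nn_sched_step(2e-2, 12, 16L), nn_sched_step(2e-2, 8, 16L),
       nn_sched_step(2e-3, 6, 16L), nn_sched_step(2e-3, 4, 16L))
}

#' @rdname default_train_schedule
#' @export
fullscale_train_schedule <- function() {
  list(nn_sched_step(1e-5, 20, 1L), nn_sched_step(1e-5, 20, 1L),
       nn_sched_step(1e-6, 20, 1L), nn_sched_step(1e-6, 10, 1L))
}

#' Detector configuration
#'
#' @param input_size working frame size, `c(rows, cols)`; images are
#'   anisotropically resized to it before proposal generation.
#' @param patch_size side of the square patch the CNN classifies.
#' @param conv_filters filter counts of the two convolutional layers.
#' @param fc_hidden width of the hidden fully connected layer.
#' @param train_schedule list of training steps; see
#'   [default_train_schedule()].
#' @param score_threshold minimum stump probability for a detection.
#' @param nms_sq_threshold suppress any box whose sq with a higher-scoring
#'   kept box exceeds this.
#' @param window_range proposal window side range in working-frame pixels;
#'   `NULL` derives it from the [scene_params()] default stump radius range
#'   (diameters 0.16--0.7 of the smaller frame dimension).
#' @param scale_step geometric step between proposal window sizes.
#' @param stride_frac stride between windows as a fraction of window side.
#' @param jitter_pos,n_neg positive-box jitter copies and negative patches
#'   sampled per scene during training.
#' @return object of class `"detector_config"`.
#' @export
detector_config <- function(input_size = c(300L, 400L), patch_size = 32L,
                            conv_filters = c(32L, 32L), fc_hidden = 64L,
                            train_schedule = default_train_schedule(),
                            score_threshold = 0.5, nms_sq_threshold = 0.3,
                            window_range = NULL, scale_step = 1.35,
                            stride_frac = 0.5,
                            jitter_pos = 3L, n_neg = 8L) {
  if (is.null(window_range))
    window_range <- round(2 * c(0.08, 0.35) * min(input_size))
  stopifnot(patch_size < min(input_size),
            score_threshold > 0, score_threshold < 1,
            nms_sq_threshold > 0, nms_sq_threshold < 1,
            window_range[1] >= patch_size / 2,
            window_range[2] <= min(input_size))
  structure(list(input_size = as.integer(input_size),
                 patch_size = as.integer(patch_size),
                 conv_filters = as.integer(conv_filters),
                 fc_hidden = as.integer(fc_hidden),
                 train_schedule = train_schedule,
                 score_threshold = score_threshold,
                 nms_sq_threshold = nms_sq_threshold,
                 window_range = window_range, scale_step = scale_step,
                 stride_frac = stride_frac,
                 jitter_pos = as.integer(jitter_pos),
                 n_neg = as.integer(n_neg)),
            class = "detector_config")
}

#' Resize an image to the detector's working frame
#'
#' Anisotropic resize (aspect ratio not preserved): e.g. a 3456 x 5184
#' photograph becomes 300 x 400. The returned per-axis scale factors map
#' working-frame boxes back to original coordinates via [map_box()].
#'
#' @param image `H x W x 3` array.
#' @param input_size target `c(rows, cols)`.
#' @return list with `image` (resized array) and `scale` = `c(sy, sx)` =
#'   original size / working size per axis.
#' @export
resize_for_detection <- function(image, input_size = c(300L, 400L)) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L || any(d[1:2] < 1))
    stop("empty image", call. = FALSE)
  list(image = resize_image(image, input_size[1], input_size[2]),
       scale = c(sy = d[1] / input_size[1], sx = d[2] / input_size[2]))
}

#' Map a working-frame box to original-image coordinates
#'
#' @param b a [bbox()] in working-frame coordinates.
#' @param scale per-axis factors `c(sy, sx)` from [resize_for_detection()].
#' @return a [bbox()] in original coordinates.
#' @export
map_box <- function(b, scale) {
  bbox(b[["x_min"]] * scale[["sx"]], b[["y_min"]] * scale[["sy"]],
       b[["x_max"]] * scale[["sx"]], b[["y_max"]] * scale[["sy"]])
}

## Crop a half-open box from an image and resample to size x size.
crop_resize <- function(image, b, size) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ys <- (floor(b[["y_min"]]) + 1L):min(H, ceiling(b[["y_max"]]))
  xs <- (floor(b[["x_min"]]) + 1L):min(W, ceiling(b[["x_max"]]))
  resize_image(image[ys, xs, , drop = FALSE], size, size)
}

## Proposal window sides for a config: geometric series through the window
## range, always including the upper endpoint so the largest stumps have a
## containing window.
window_sizes <- function(config) {
  s <- config$window_range[1]
  out <- c()
  while (s < config$window_range[2]) {
    out <- c(out, round(s))
    s <- s * config$scale_step
  }
  out <- c(out, config$window_range[2])
  unique(pmin(out, min(config$input_size)))
}

## ---- training -------------------------------------------------------------

## Random box of a given side that has sq < 0.25 with every ground-truth box.
sample_negative_box <- function(H, W, side, gt_boxes) {
  for (i in 1:30) {
    x0 <- stats::runif(1, 0, W - side)
    y0 <- stats::runif(1, 0, H - side)
    b <- bbox(x0, y0, x0 + side, y0 + side)
    if (length(gt_boxes) == 0L ||
        all(vapply(gt_boxes, function(g) sq_score(b, g)$sq, numeric(1)) < 0.25))
      return(b)
  }
  NULL
}

## Badly-localized copy of a ground-truth box (sq in [0.15, 0.45] with every
## ground truth): teaches the scorer to reject partial overlaps, which is
## what makes score-thresholded windows concentrate on the object.
sample_hard_negative_box <- function(H, W, g, gt_boxes) {
  w <- g[["x_max"]] - g[["x_min"]]; h <- g[["y_max"]] - g[["y_min"]]
  for (i in 1:30) {
    f <- stats::runif(1, 0.6, 1.8)
    dx <- stats::runif(1, -0.8, 0.8) * w; dy <- stats::runif(1, -0.8, 0.8) * h
    cx <- (g[["x_min"]] + g[["x_max"]]) / 2 + dx
    cy <- (g[["y_min"]] + g[["y_max"]]) / 2 + dy
    x0 <- clamp(cx - f * w / 2, 0, W - 8); y0 <- clamp(cy - f * h / 2, 0, H - 8)
    x1 <- clamp(cx + f * w / 2, x0 + 8, W); y1 <- clamp(cy + f * h / 2, y0 + 8, H)
    b <- bbox(x0, y0, x1, y1)
    s <- vapply(gt_boxes, function(gg) sq_score(b, gg)$sq, numeric(1))
    if (max(s) >= 0.15 && max(s) <= 0.45) return(b)
  }
  NULL
}

## Positive / negative 32x32 patches from labeled scenes (working frame).
collect_patches <- function(scenes, config) {
  ps <- config$patch_size
  pats <- list(); labs <- integer(0)
  for (sc in scenes) {
    gt <- lapply(sc$stumps, `[[`, "bbox")
    H <- sc$height; W <- sc$width
    for (g in gt) {
      w <- g[["x_max"]] - g[["x_min"]]; h <- g[["y_max"]] - g[["y_min"]]
      boxes <- list(g)
      ## jittered positives emulate the views the proposal grid offers: up
      ## to a scale-step of size mismatch and a quarter-window offset, but
      ## only views a matcher would still score well (sq >= 0.6)
      for (j in seq_len(config$jitter_pos)) {
        for (try in 1:20) {
          dx <- stats::runif(1, -0.15, 0.15) * w
          dy <- stats::runif(1, -0.15, 0.15) * h
          f <- stats::runif(1, 0.85, 1.25)
          cx <- (g[["x_min"]] + g[["x_max"]]) / 2 + dx
          cy <- (g[["y_min"]] + g[["y_max"]]) / 2 + dy
          b <- bbox(clamp(cx - f * w / 2, 0, W - 2),
                    clamp(cy - f * h / 2, 0, H - 2),
                    clamp(cx + f * w / 2, 2, W),
                    clamp(cy + f * h / 2, 2, H))
          if (sq_score(b, g)$sq >= 0.65) break
        }
        boxes[[j + 1L]] <- b
      }
      for (b in boxes) {
        pats[[length(pats) + 1L]] <- crop_resize(sc$image, b, ps)
        labs <- c(labs, 1L)
      }
    }
    n_hard <- if (length(gt)) config$n_neg %/% 2L else 0L
    for (j in seq_len(config$n_neg - n_hard)) {
      side <- stats::runif(1, config$window_range[1], config$window_range[2])
      side <- min(side, H - 2, W - 2)
      nb <- sample_negative_box(H, W, side, gt)
      if (is.null(nb)) next
      pats[[length(pats) + 1L]] <- crop_resize(sc$image, nb, ps)
      labs <- c(labs, 2L)
    }
    for (j in seq_len(n_hard)) {
      g <- gt[[1L + (j - 1L) %% length(gt)]]
      nb <- sample_hard_negative_box(H, W, g, gt)
      if (is.null(nb)) next
      pats[[length(pats) + 1L]] <- crop_resize(sc$image, nb, ps)
      labs <- c(labs, 2L)
    }
  }
  X <- array(0, dim = c(ps, ps, 3L, length(pats)))
  for (i in seq_along(pats)) X[, , , i] <- pats[[i]]
  list(X = X, y = labs)
}

#' Train the stump detector
#'
#' Builds a training set of positive (ground-truth box, with jittered copies)
#' and negative (background and badly-localized) patches from labeled scenes,
#' then trains the patch CNN with the configured four-step SGD-with-momentum
#' schedule. Between the first two steps and the two fine-tuning steps, the
#' partially trained detector is run on training scenes and its own false
#' positives (windows with sq < 0.45 against every ground-truth box) are
#' added as mined hard negatives, so the fine-tuning steps concentrate on the
#' proposals the network currently mislabels.
#'
#' @param scenes list of [render_scene()] scenes (working-frame size).
#' @param config a [detector_config()].
#' @param seed integer seed controlling patch sampling, weight
#'   initialization and mini-batch order.
#' @param verbose print per-epoch training accuracy.
#' @return object of class `"stump_detector"`.
#' @export
train_detector <- function(scenes, config = detector_config(), seed = 1L,
                           verbose = FALSE) {
  if (length(scenes) == 0L) stop("empty training set", call. = FALSE)
  if (!any(vapply(scenes, function(s) length(s$stumps) > 0L, logical(1))))
    stop("training set contains no stump", call. = FALSE)
  seeds <- derive_seeds(seed, 4L)
  data <- with_seed(seeds[1], collect_patches(scenes, config))
  ps <- config$patch_size
  arch <- list(nn_conv(config$conv_filters[1]), nn_relu(),
               nn_conv(config$conv_filters[2]), nn_relu(), nn_pool(),
               nn_flatten(), nn_fc(config$fc_hidden), nn_relu(), nn_fc(2L))
  net <- nn_init(arch, c(ps, ps, 3L), seed = seeds[2])
  sched <- config$train_schedule
  half <- min(2L, length(sched) - 1L)
  net <- nn_train(net, data$X, data$y, sched[seq_len(half)],
                  seed = seeds[3], verbose = verbose)

  ## fine-tuning steps, each preceded by a mining pass; mined negatives are
  ## duplicated so they carry weight against the larger base set
  X <- data$X; y <- data$y
  n_mined <- 0L
  rest <- sched[-seq_len(half)]
  for (si in seq_along(rest)) {
    model <- structure(list(net = net, config = config,
                            classes = c("stump", "background")),
                       class = "stump_detector")
    mined <- with_seed(seeds[4] + si,
                       mine_hard_negatives(model, scenes,
                                           max_scenes = length(scenes),
                                           per_scene = 8L))
    n_mined <- n_mined + length(mined)
    if (length(mined)) {
      mined <- rep(mined, 2L)
      Xm <- array(0, dim = c(ps, ps, 3L, length(mined)))
      for (i in seq_along(mined)) Xm[, , , i] <- mined[[i]]
      X <- array(c(X, Xm), dim = c(ps, ps, 3L, length(y) + length(mined)))
      y <- c(y, rep(2L, length(mined)))
    }
    net <- nn_train(net, X, y, rest[si], seed = seeds[3] + si,
                    verbose = verbose)
  }

  structure(list(net = net, config = config,
                 classes = c("stump", "background"),
                 n_train_patches = length(y),
                 n_mined_negatives = n_mined),
            class = "stump_detector")
}

## Run the current detector over (a subsample of) the training scenes and
## crop the detections that the one-to-one sq matching protocol would count
## as false positives as additional negative patches. Only unmatched
## detections covering less than half of every stump (segmentation-overlap
## O/L < 0.5) are mined: that captures background windows, rim-less
## sub-boxes inside a stump, and cross-scale duplicates, while sparing
## near-miss full views of a stump, whose appearance matches the positives
## (labeling those negative destroys recall on coarse proposal grids).
mine_hard_negatives <- function(model, scenes, max_scenes = 40L,
                                per_scene = 8L) {
  cfg <- model$config
  if (length(scenes) > max_scenes)
    scenes <- scenes[sort(sample.int(length(scenes), max_scenes))]
  out <- list()
  for (sc in scenes) {
    dets <- detect(model, sc$image)
    if (nrow(dets) == 0L) next
    gt <- lapply(sc$stumps, `[[`, "bbox")
    matched <- if (length(gt))
      match_detections(dets, gt, sq_threshold = 0.5)$matches$detection
    else integer(0)
    taken <- 0L
    for (i in setdiff(seq_len(nrow(dets)), matched)) {
      if (taken >= per_scene) break
      b <- bbox(dets$x_min[i], dets$y_min[i], dets$x_max[i], dets$y_max[i])
      ovl <- if (length(gt))
        max(vapply(gt, function(g) sq_score(b, g)$segmentation_overlap,
                   numeric(1)))
      else 0
      if (ovl < 0.5) {
        out[[length(out) + 1L]] <- crop_resize(sc$image, b, cfg$patch_size)
        taken <- taken + 1L
      }
    }
  }
  out
}

#' @export
print.stump_detector <- function(x, ...) {
  cat(sprintf("<stump_detector: %dx%d patch CNN, trained on %d patches>\n",
              x$config$patch_size, x$config$patch_size, x$n_train_patches))
  invisible(x)
}

## ---- detection ------------------------------------------------------------

## Score all sliding windows of one pyramid level. The two conv layers (and
## pool) run once over the whole level image (fully convolutional); each
## window position then gathers its pooled 14x14 feature patch for the FC
## head. Window positions are restricted to odd pixel offsets so patches
## align with the 2x2 pooling grid, making this exactly equivalent to
## cropping and classifying each 32x32 window individually.
score_level <- function(model, image, side) {
  cfg <- model$config
  ps <- cfg$patch_size
  ly <- model$net$layers
  H <- dim(image)[1]; W <- dim(image)[2]
  f <- ps / side
  h <- max(ps, round(H * f)); w <- max(ps, round(W * f))
  im <- resize_image(image, h, w)

  A <- array(aperm(im, c(3L, 1L, 2L)), dim = c(3L, h, w, 1L))  # channel-first
  A <- conv_forward(ly[[1]], A)$out; A <- A * (A > 0)
  A <- conv_forward(ly[[3]], A)$out; A <- A * (A > 0)
  FM <- pool_forward(A)$out                          # (F, hp, wp, 1)
  Fc <- dim(FM)[1]; hp <- dim(FM)[2]; wp <- dim(FM)[3]
  dim(FM) <- dim(FM)[1:3]
  fs <- (ps - 2L * (ly[[1]]$ksize - 1L)) %/% 2L      # feature patch side (14)

  stride <- max(2L, 2L * round(ps * cfg$stride_frac / 2))   # even stride
  ymax <- h - ps + 1L; xmax <- w - ps + 1L
  odd <- function(v) pmax(1L, v - (1L - v %% 2L))    # snap down to odd
  ypos <- sort(unique(odd(c(seq(1L, ymax, by = stride), ymax))))
  xpos <- sort(unique(odd(c(seq(1L, xmax, by = stride), xmax))))
  ypos <- ypos[(ypos + 1L) %/% 2L + fs - 1L <= hp]
  xpos <- xpos[(xpos + 1L) %/% 2L + fs - 1L <= wp]
  grid <- expand.grid(y = ypos, x = xpos)
  n <- nrow(grid)
  if (n == 0L) return(NULL)

  ## gather flattened (c, y, x)-ordered feature patches for all positions
  e <- as.vector(outer(seq_len(Fc),
                       as.vector(outer((0:(fs - 1L)) * Fc,
                                       (0:(fs - 1L)) * Fc * hp, `+`)), `+`))
  p0 <- ((grid$y + 1L) %/% 2L - 1L) * Fc + ((grid$x + 1L) %/% 2L - 1L) * Fc * hp
  P <- FM[rep(e, times = n) + rep(p0, each = length(e))]
  dim(P) <- c(length(e), n)

  Z <- ly[[7]]$W %*% P + ly[[7]]$b                    # FC hidden
  Z <- Z * (Z > 0)
  S <- softmax_cols(ly[[9]]$W %*% Z + ly[[9]]$b)

  fy <- H / h; fx <- W / w                            # back to working frame
  data.frame(x_min = (grid$x - 1) * fx, y_min = (grid$y - 1) * fy,
             x_max = pmin(W, (grid$x - 1 + ps) * fx),
             y_max = pmin(H, (grid$y - 1 + ps) * fy),
             score = S[1L, ])
}

#' Non-maximum suppression by segmentation quality
#'
#' Greedy: keep the highest-scoring box, drop any remaining box whose
#' [sq_score()] with a kept box exceeds the threshold; repeat. Idempotent.
#'
#' @param detections data frame with `x_min, y_min, x_max, y_max, score`.
#' @param sq_threshold suppression threshold.
#' @return the kept rows, sorted by descending score.
#' @export
nms_detections <- function(detections, sq_threshold = 0.3) {
  if (nrow(detections) == 0L) return(detections)
  d <- detections[order(-detections$score), , drop = FALSE]
  boxes <- as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")])
  keep <- logical(nrow(d)); alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    b <- bbox(boxes[i, 1], boxes[i, 2], boxes[i, 3], boxes[i, 4])
    later <- which(alive & seq_len(nrow(d)) > i)
    if (length(later))
      alive[later[sq_vec(b, boxes[later, , drop = FALSE]) > sq_threshold]] <- FALSE
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect stumps in an image
#'
#' The image is resized to the working frame if needed; proposals are scored
#' at every pyramid level and thresholded, then non-maximum suppression keeps
#' one box per object. Returned boxes are in working-frame coordinates
#' (`detection_scale` attribute maps back to the original frame).
#'
#' @param model a trained [train_detector()] model.
#' @param image `H x W x 3` array.
#' @return data frame of detections (`x_min, y_min, x_max, y_max, score`),
#'   scores non-increasing.
#' @export
detect <- function(model, image) {
  if (!inherits(model, "stump_detector"))
    stop("`model` is not a trained stump_detector", call. = FALSE)
  cfg <- model$config
  rs <- resize_for_detection(image, cfg$input_size)
  dets <- do.call(rbind, lapply(window_sizes(cfg), function(s)
    score_level(model, rs$image, s)))
  dets <- dets[dets$score >= cfg$score_threshold, , drop = FALSE]
  dets <- nms_detections(dets, cfg$nms_sq_threshold)
  attr(dets, "detection_scale") <- rs$scale
  dets
}

## Convert a detections data frame to a list of bbox objects.
detections_to_boxes <- function(detections) {
  lapply(seq_len(nrow(detections)), function(i)
    bbox(detections$x_min[i], detections$y_min[i],
         detections$x_max[i], detections$y_max[i]))
}
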