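## Feature extraction for rot classification: (a) bag-of-visual-words over
## local scale-invariant descriptors, (b) penultimate-layer activations of a
## CNN backbone.
##
## The local descriptor is an upright SIFT-family descriptor: keypoints are
## difference-of-Gaussian extrema over a scale pyramid, described by 4x4
## spatial cells of 8-bin gradient-orientation histograms (128 dimensions),
## sampled proportionally to keypoint scale, L2-normalized with 0.2 clipping.

#' Extract local scale-invariant descriptors
#'
#' Difference-of-Gaussian keypoint detection over `n_octaves` octaves with a
#' gradient-orientation-histogram descriptor (128-d, upright). Keypoint
#' coordinates and scales are reported in input-image pixels.
#'
#' @param image `H x W x 3` (or grayscale `H x W`) array in `[0,1]`.
#' @param n_octaves number of pyramid octaves.
#' @param peak_threshold minimum |DoG| response at a keypoint.
#' @param max_keypoints keep at most this many strongest keypoints.
#' @return list with `descriptors` (n x 128 matrix, 0 rows allowed) and
#'   `keypoints` (data frame: `x`, `y`, `scale`, `response`; 0-based pixel
#'   coordinates).
#' @export
extract_descriptors <- function(image, n_octaves = 4L, peak_threshold = 0.003,
                                max_keypoints = 300L) {
  gray <- to_gray(image)
  H0 <- dim(gray)[1]; W0 <- dim(gray)[2]
  ## replicate-pad so keypoints on object rims at the crop border (tight
  ## bounding-box crops put the bark ring right at the edge) stay describable
  pad <- 20L
  gray <- gray[c(rep(1L, pad), seq_len(H0), rep(H0, pad)),
               c(rep(1L, pad), seq_len(W0), rep(W0, pad))]
  desc <- list(); kp <- list()
  base <- gray
  s0 <- 1.6; kk <- sqrt(2)
  for (o in seq_len(n_octaves) - 1L) {
    H <- dim(base)[1]; W <- dim(base)[2]
    if (min(H, W) < 28) break
    ## four blur levels -> three DoG levels -> extrema on the middle one
    G <- lapply(0:3, function(i) ebi_blur(base, s0 * kk^i))
    D <- lapply(1:3, function(i) G[[i + 1L]] - G[[i]])
    ext <- dog_extrema(D, peak_threshold)
    if (nrow(ext) > 0L) {
      sig <- s0 * kk                      # scale of the middle DoG level
      dd <- describe_keypoints(G[[2L]], ext, sig)
      if (nrow(dd$descriptors) > 0L) {
        f <- 2^o
        x <- dd$keypoints$x * f - pad; y <- dd$keypoints$y * f - pad
        inb <- x >= 0 & x < W0 & y >= 0 & y < H0
        if (any(inb)) {
          desc[[length(desc) + 1L]] <- dd$descriptors[inb, , drop = FALSE]
          kp[[length(kp) + 1L]] <- data.frame(
            x = x[inb], y = y[inb], scale = sig * f,
            response = dd$keypoints$response[inb])
        }
      }
    }
    base <- resize_image(base, max(1L, H %/% 2L), max(1L, W %/% 2L))
  }
  if (length(desc) == 0L)
    return(list(descriptors = matrix(0, 0L, 128L),
                keypoints = data.frame(x = numeric(0), y = numeric(0),
                                       scale = numeric(0), response = numeric(0))))
  descriptors <- do.call(rbind, desc)
  keypoints <- do.call(rbind, kp)
  if (nrow(keypoints) > max_keypoints) {
    keep <- order(-abs(keypoints$response))[seq_len(max_keypoints)]
    descriptors <- descriptors[keep, , drop = FALSE]
    keypoints <- keypoints[keep, , drop = FALSE]
    rownames(keypoints) <- NULL
  }
  list(descriptors = descriptors, keypoints = keypoints)
}

ebi_blur <- function(gray, sigma) {
  cpp_gauss_blur(gray, sigma)
}

## Local extrema of the middle DoG level against its 3x3x3 neighborhood.
## Returns matrix with columns (row, col, response), 1-based interior coords.
dog_extrema <- function(D, threshold) {
  H <- dim(D[[1L]])[1]; W <- dim(D[[1L]])[2]
  if (H < 3L || W < 3L) return(matrix(0, 0L, 3L))
  ri <- 2:(H - 1L); ci <- 2:(W - 1L)
  M <- D[[2L]][ri, ci, drop = FALSE]
  is_max <- abs(M) > threshold
  is_min <- is_max
  for (lev in 1:3) {
    for (dy in -1:1) for (dx in -1:1) {
      if (lev == 2L && dy == 0L && dx == 0L) next
      Nb <- D[[lev]][ri + dy, ci + dx, drop = FALSE]
      is_max <- is_max & (M > Nb)
      is_min <- is_min & (M < Nb)
      if (!any(is_max) && !any(is_min)) break
    }
  }
  idx <- which(is_max | is_min, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(0, 0L, 3L))
  cbind(idx[, 1L] + 1L, idx[, 2L] + 1L, M[idx])
}

## 4x4-cell x 8-orientation-bin descriptors around keypoints on one blurred
## pyramid level. `ext` holds (row, col, response); sigma is the level scale.
describe_keypoints <- function(G, ext, sigma) {
  H <- dim(G)[1]; W <- dim(G)[2]
  ## image gradients (central differences)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1L)] <- (G[, 3:W] - G[, 1:(W - 2L)]) / 2
  gy[2:(H - 1L), ] <- (G[3:H, ] - G[1:(H - 2L), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)                      # (-pi, pi]

  step <- 0.9 * sigma                       # sample spacing
  half <- 8L                                # 16x16 sample grid
  off <- (seq_len(2L * half) - half - 0.5) * step
  margin <- ceiling(half * step) + 1L
  ok <- ext[, 1L] > margin & ext[, 1L] <= H - margin &
    ext[, 2L] > margin & ext[, 2L] <= W - margin
  ext <- ext[ok, , drop = FALSE]
  n <- nrow(ext)
  if (n == 0L)
    return(list(descriptors = matrix(0, 0L, 128L),
                keypoints = data.frame(x = numeric(0), y = numeric(0),
                                       response = numeric(0))))

  ## precompute per-sample cell index and Gaussian weight (shared by all kps)
  gy_off <- matrix(off, 16L, 16L); gx_off <- matrix(off, 16L, 16L, byrow = TRUE)
  cell <- (pmin(3L, (seq_len(16L) - 1L) %/% 4L))
  cell_idx <- matrix(cell, 16L, 16L) + 4L * matrix(cell, 16L, 16L, byrow = TRUE)
  wgt <- exp(-(gy_off^2 + gx_off^2) / (2 * (half * step)^2))

  descs <- matrix(0, n, 128L)
  for (i in seq_len(n)) {
    ys <- round(ext[i, 1L] + gy_off); xs <- round(ext[i, 2L] + gx_off)
    lin <- cbind(as.vector(ys), as.vector(xs))
    m <- mag[lin] * as.vector(wgt)
    obin <- pmin(7L, floor((ori[lin] + pi) / (2 * pi) * 8))
    bins <- as.vector(cell_idx) * 8L + obin + 1L      # 1..128
    h <- numeric(128L)
    acc <- rowsum(m, bins)
    h[as.integer(rownames(acc))] <- acc
    nz <- sqrt(sum(h^2))
    if (nz > 0) {
      h <- pmin(h / nz, 0.2)
      h <- h / sqrt(sum(h^2))
    }
    descs[i, ] <- h
  }
  list(descriptors = descs,
       keypoints = data.frame(x = ext[, 2L] - 1, y = ext[, 1L] - 1,
                              response = ext[, 3L]))
}

#' Build a visual vocabulary by k-means
#'
#' Clusters pooled local descriptors into `k` visual words with
#' [stats::kmeans()] under a fixed seed; each cluster center is one word.
#'
#' @param descriptor_sets list of descriptor matrices (rows = descriptors),
#'   or a single matrix.
#' @param k number of visual words (reference configuration: 500).
#' @param seed integer seed.
#' @param iter_max maximum k-means iterations.
#' @return object of class `"bof_vocabulary"`: `centers` (k x d), `k`,
#'   `descriptor_kind`.
#' @export
build_vocabulary <- function(descriptor_sets, k = 500L, seed = 1L,
                             iter_max = 20L) {
  X <- if (is.matrix(descriptor_sets)) descriptor_sets
       else do.call(rbind, descriptor_sets)
  if (is.null(X) || nrow(X) < k)
    stop(sprintf("need at least k = %d descriptors, got %d", k,
                 if (is.null(X)) 0L else nrow(X)), call. = FALSE)
  km <- with_seed(seed,
                  stats::kmeans(X, centers = k, iter.max = iter_max,
                                nstart = 1L))
  structure(list(centers = unname(km$centers), k = as.integer(k),
                 descriptor_kind = "dog-gradient-histogram-128"),
            class = "bof_vocabulary")
}

#' @export
print.bof_vocabulary <- function(x, ...) {
  cat(sprintf("<bof_vocabulary: %d words, %d-d %s descriptors>\n",
              x$k, ncol(x$centers), x$descriptor_kind))
  invisible(x)
}

#' Encode an image as a bag-of-visual-words histogram
#'
#' Each descriptor is assigned to its nearest vocabulary center (Euclidean)
#' and the word histogram is normalized to sum 1. An image with no
#' descriptors encodes to the all-zero vector.
#'
#' @param image image array, or a precomputed descriptor matrix.
#' @param vocab a [build_vocabulary()] vocabulary.
#' @return numeric vector of length `vocab$k`.
#' @export
encode_bof <- function(image, vocab) {
  D <- if (is.matrix(image)) image else extract_descriptors(image)$descriptors
  if (ncol(D) != ncol(vocab$centers))
    stop("descriptor dimension does not match vocabulary", call. = FALSE)
  h <- numeric(vocab$k)
  if (nrow(D) == 0L) return(h)
  ## nearest center: argmin ||d||^2 - 2 d.c + ||c||^2
  cross <- D %*% t(vocab$centers)
  cn <- rowSums(vocab$centers^2)
  assign_ <- max.col(sweep(2 * cross, 2L, cn, `-`), ties.method = "first")
  tab <- tabulate(assign_, nbins = vocab$k)
  tab / sum(tab)
}

## ---- desk-scale CNN backbone ---------------------------------------------

backbone_arch <- function(n_classes = 3L) {
  list(nn_conv(16L), nn_relu(), nn_pool(),
       nn_conv(32L), nn_relu(), nn_pool(),
       nn_conv(64L), nn_relu(), nn_pool(),
       nn_flatten(), nn_fc(128L), nn_relu(), nn_fc(n_classes))
}

#' Train the desk-scale CNN backbone
#'
#' A small three-conv-block CNN (16/32/64 filters, FC-128 penultimate layer)
#' pretrained on an auxiliary synthetic task: rot-severity classification of
#' stump crops from an independently generated scene set. Its penultimate
#' activations serve as generic stump features for the feature+SVM
#' classifier, and the network is the starting point for fine-tuning.
#'
#' @param scenes optional list of labeled scenes to pretrain on; when `NULL`,
#'   an auxiliary set of `n_aux_per_class` scenes per severity class is
#'   generated internally (no occlusion, mild lighting jitter).
#' @param n_aux_per_class auxiliary scenes per class when `scenes` is `NULL`.
#' @param input_size square input side in pixels.
#' @param schedule training schedule (list of steps).
#' @param seed integer seed.
#' @param verbose print per-epoch accuracy.
#' @return object of class `"cnn_backbone"`: `net`, `input_size`,
#'   `feature_dim` (128), `feature_layer`.
#' @export
train_backbone <- function(scenes = NULL, n_aux_per_class = 40L,
                           input_size = 48L,
                           schedule = list(nn_sched_step(2e-2, 12, 16L),
                                           nn_sched_step(2e-3, 6, 16L)),
                           seed = 1L, verbose = FALSE) {
  seeds <- derive_seeds(seed, 4L)
  if (is.null(scenes)) {
    pars <- scene_params(occlusion_fraction = 0.05, lighting_gain = c(0.85, 1.15))
    scenes <- generate_scene_set(rep(n_aux_per_class, 3L), pars,
                                 seed = seeds[1])
  }
  crops <- list(); y <- integer(0)
  for (sc in scenes) for (st in sc$stumps) {
    crops[[length(crops) + 1L]] <- crop_resize(sc$image, st$bbox, input_size)
    y <- c(y, match(as.character(st$rot_class), ROT_CLASSES))
  }
  X <- array(0, dim = c(input_size, input_size, 3L, length(crops)))
  for (i in seq_along(crops)) X[, , , i] <- crops[[i]]
  net <- nn_init(backbone_arch(3L), c(input_size, input_size, 3L),
                 seed = seeds[2])
  net <- nn_train(net, X, y, schedule, seed = seeds[3], verbose = verbose)
  structure(list(net = net, input_size = as.integer(input_size),
                 feature_dim = 128L,
                 feature_layer = 12L),     # ReLU after the FC-128 layer
            class = "cnn_backbone")
}

#' @export
print.cnn_backbone <- function(x, ...) {
  cat(sprintf("<cnn_backbone: %dx%d input, %d-d penultimate features>\n",
              x$input_size, x$input_size, x$feature_dim))
  invisible(x)
}

#' Extract penultimate-layer CNN features
#'
#' Runs the backbone up to the last fully connected layer before the
#' classification layer and returns its activations as a flat feature
#' vector, one row per image.
#'
#' @param images one image array, or a list of image arrays.
#' @param backbone a [train_backbone()] model (or a fine-tuned classifier's
#'   backbone).
#' @return numeric matrix (n images x feature_dim).
#' @export
extract_cnn_features <- function(images, backbone) {
  if (!inherits(backbone, "cnn_backbone"))
    stop("`backbone` must be a cnn_backbone", call. = FALSE)
  if (!is.list(images)) images <- list(images)
  s <- backbone$input_size
  X <- array(0, dim = c(s, s, 3L, length(images)))
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!identical(dim(im)[1:2], c(s, s))) im <- resize_image(im, s, s)
    X[, , , i] <- im
  }
  A <- nn_forward(backbone$net, X, upto = backbone$feature_layer)$out
  t(A)
}
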