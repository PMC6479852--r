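## Synthetic post-harvest scene generator.
##
## Scenes emulate close-range RGB photographs of freshly cut Norway spruce
## stumps on a cluttered forest floor: a pale ringed sawn surface with a dark
## bark rim, optionally carrying a darker high-noise rot region; needles,
## branch pieces and sawdust as background clutter and as occluders; lighting
## gain/gradient jitter and soft shadows. Ground-truth masks are captured
## before lighting is applied, so labels are exact by construction.

ROT_CLASSES <- c("NO_ROT", "ROT_LT_50", "ROT_GE_50")

#' Rot severity class labels
#'
#' Severity follows industry grading of the cut surface: no rot at all
#' (saw-timber quality), rot covering less than half the surface, and rot
#' covering half or more.
#'
#' @param n_classes 3 (default) for the severity classes, or 2 for the
#'   binary rot/no-rot setting.
#' @return character vector of class labels in their fixed order.
#' @export
rot_class_levels <- function(n_classes = 3) {
  if (n_classes == 3) ROT_CLASSES
  else if (n_classes == 2) c("NO_ROT", "ROT")
  else stop("n_classes must be 2 or 3", call. = FALSE)
}

#' Severity class from a rot area ratio
#'
#' @param r rot-to-stump pixel area ratio in `[0, 1]`.
#' @return factor with levels [rot_class_levels()]: `NO_ROT` for r = 0,
#'   `ROT_LT_50` for 0 < r < 0.5, `ROT_GE_50` for r >= 0.5.
#' @examples
#' class_from_ratio(c(0, 0.49, 0.5, 1))
#' @export
class_from_ratio <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("rot ratio must lie in [0, 1]", call. = FALSE)
  lab <- ifelse(r == 0, "NO_ROT", ifelse(r < 0.5, "ROT_LT_50", "ROT_GE_50"))
  factor(lab, levels = ROT_CLASSES)
}

#' Rot area ratio from masks
#'
#' The ratio is computed pixelwise: the number of rot pixels divided by the
#' number of stump-surface pixels.
#'
#' @param rot_mask,stump_mask logical matrices of identical dimensions;
#'   every rot pixel must lie on the stump.
#' @return fraction in `[0, 1]`.
#' @export
rbr_ratio <- function(rot_mask, stump_mask) {
  if (!identical(dim(rot_mask), dim(stump_mask)))
    stop("masks must share dimensions", call. = FALSE)
  ns <- sum(stump_mask != 0)
  if (ns == 0L) stop("stump mask is empty", call. = FALSE)
  if (any(rot_mask != 0 & stump_mask == 0))
    stop("rot mask extends outside the stump mask", call. = FALSE)
  sum(rot_mask != 0) / ns
}

#' Scene generation parameters
#'
#' @param image_height,image_width scene size in pixels (default 300 x 400,
#'   the working resolution of the detector).
#' @param stump_radius_range stump radius as a fraction of the smaller image
#'   dimension; the default 0.08--0.35 emulates varying camera distance.
#' @param target_rbr_ratio desired rot area ratio in `[0, 1]`; the generator
#'   hits it to within one pixel of stump area.
#' @param occlusion_fraction fraction (0--0.4) of the stump surface covered
#'   by clutter drawn over it.
#' @param lighting_gain range of the multiplicative lighting jitter.
#' @param shadow logical; allow a soft elliptical shadow.
#' @param n_stumps number of stumps in the scene (0 gives a pure background
#'   scene; default 1).
#' @param clutter_density clutter elements per 10,000 background pixels.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   scenes.
#' @return an object of class `"scene_params"`.
#' @export
scene_params <- function(image_height = 300, image_width = 400,
                         stump_radius_range = c(0.08, 0.35),
                         target_rbr_ratio = 0,
                         occlusion_fraction = 0.1,
                         lighting_gain = c(0.7, 1.3),
                         shadow = TRUE,
                         n_stumps = 1,
                         clutter_density = 6,
                         seed = 1L) {
  p <- list(image_height = image_height, image_width = image_width,
            stump_radius_range = stump_radius_range,
            target_rbr_ratio = target_rbr_ratio,
            occlusion_fraction = occlusion_fraction,
            lighting_gain = lighting_gain, shadow = isTRUE(shadow),
            n_stumps = n_stumps, clutter_density = clutter_density,
            seed = as.integer(seed))
  validate_scene_params(p)
  class(p) <- "scene_params"
  p
}

validate_scene_params <- function(p) {
  stopifnot(p$image_height >= 32, p$image_width >= 32)
  rr <- p$stump_radius_range
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] <= 0 || rr[2] > 0.45)
    stop("stump_radius_range must be an increasing range within (0, 0.45]",
         call. = FALSE)
  if (p$target_rbr_ratio < 0 || p$target_rbr_ratio > 1)
    stop("target_rbr_ratio must lie in [0, 1]", call. = FALSE)
  if (p$occlusion_fraction < 0 || p$occlusion_fraction > 0.4)
    stop("occlusion_fraction must lie in [0, 0.4]", call. = FALSE)
  lg <- p$lighting_gain
  if (length(lg) != 2L || lg[1] > lg[2] || lg[1] <= 0)
    stop("lighting_gain must be a positive increasing range", call. = FALSE)
  if (p$n_stumps < 0) stop("n_stumps must be >= 0", call. = FALSE)
  if (p$n_stumps == 0 && p$target_rbr_ratio > 0)
    stop("target_rbr_ratio > 0 is unreachable with no stump in the scene",
         call. = FALSE)
  invisible(p)
}

## ---- low-level painters ---------------------------------------------------
##
## Clutter elements are generated as (pixel index, colour) records and painted
## in a single batched assignment per channel; in-draw-order concatenation with
## duplicate indices means later elements correctly overpaint earlier ones.

## Linear pixel indices (into an H x W matrix) of an element, bounds-clipped.
element_lin <- function(idx, H, W) {
  keep <- idx[, 1] >= 1 & idx[, 1] <= H & idx[, 2] >= 1 & idx[, 2] <= W
  idx <- idx[keep, , drop = FALSE]
  idx[, 1] + (idx[, 2] - 1L) * H
}

## Paint a list of elements (each: list(lin, col, noise_sd)) onto img.
paint_elements <- function(img, elements) {
  if (length(elements) == 0L) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]; HW <- H * W
  lin <- unlist(lapply(elements, `[[`, "lin"), use.names = FALSE)
  n_each <- vapply(elements, function(e) length(e$lin), integer(1))
  jit <- stats::rnorm(length(lin), 0,
                      rep(vapply(elements, `[[`, numeric(1), "noise_sd"), n_each))
  r <- clamp(rep(vapply(elements, function(e) e$col[1], numeric(1)), n_each) + jit)
  g <- clamp(rep(vapply(elements, function(e) e$col[2], numeric(1)), n_each) + jit)
  b <- clamp(rep(vapply(elements, function(e) e$col[3], numeric(1)), n_each) + jit * 0.8)
  img[c(lin, lin + HW, lin + 2L * HW)] <- c(r, g, b)
  img
}

## Pixel indices of a thick line segment.
line_px <- function(x0, y0, x1, y1, width) {
  len <- max(abs(x1 - x0), abs(y1 - y0), 1)
  t <- seq(0, 1, length.out = ceiling(len) + 1L)
  xs <- x0 + t * (x1 - x0); ys <- y0 + t * (y1 - y0)
  if (width > 1) {
    dx <- (y0 - y1) / len; dy <- (x1 - x0) / len   # unit normal
    off <- seq(-width / 2, width / 2, by = 0.5)
    xs <- outer(xs, off * dx, `+`); ys <- outer(ys, off * dy, `+`)
  }
  unique(cbind(round(as.vector(ys)) + 1L, round(as.vector(xs)) + 1L))
}

## Pixel indices of a filled rotated ellipse.
ellipse_px <- function(cx, cy, rx, ry, ang) {
  r <- max(rx, ry)
  ys <- seq(floor(cy - r), ceiling(cy + r))
  xs <- seq(floor(cx - r), ceiling(cx + r))
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs)) - cy
  u <- X * cos(ang) + Y * sin(ang)
  v <- -X * sin(ang) + Y * cos(ang)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(ys[idx[, 1]] + 1L, xs[idx[, 2]] + 1L)
}

## One random clutter element (needle / branch piece / sawdust patch),
## centred near (cx, cy). Returns list(lin, col, noise_sd).
clutter_element <- function(cx, cy, H, W) {
  kind <- sample.int(3L, 1L, prob = c(0.55, 0.2, 0.25))
  if (kind == 1L) {          # needle: thin short line, dull green/brown
    ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 12, 45)
    col <- c(stats::runif(1, 0.15, 0.35), stats::runif(1, 0.25, 0.42),
             stats::runif(1, 0.08, 0.18))
    idx <- line_px(cx - cos(ang) * len / 2, cy - sin(ang) * len / 2,
                   cx + cos(ang) * len / 2, cy + sin(ang) * len / 2,
                   stats::runif(1, 1, 2))
  } else if (kind == 2L) {   # branch piece: thicker line, dark brown
    ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 30, 90)
    g <- stats::runif(1, 0.18, 0.3)
    col <- c(g * 1.4, g, g * 0.55)
    idx <- line_px(cx - cos(ang) * len / 2, cy - sin(ang) * len / 2,
                   cx + cos(ang) * len / 2, cy + sin(ang) * len / 2,
                   stats::runif(1, 3, 6))
  } else {                   # sawdust patch: small pale ellipse
    col <- c(stats::runif(1, 0.75, 0.9), stats::runif(1, 0.65, 0.8),
             stats::runif(1, 0.45, 0.6))
    idx <- ellipse_px(cx, cy, stats::runif(1, 3, 9), stats::runif(1, 2, 6),
                      stats::runif(1, 0, pi))
  }
  list(lin = element_lin(idx, H, W), col = col, noise_sd = 0.04)
}

## Low-frequency value noise: coarse uniform grid upsampled to H x W.
smooth_noise <- function(H, W, cells = 8) {
  coarse <- matrix(stats::runif(cells * cells), cells, cells)
  from_ebimage(EBImage::resize(as_ebimage(coarse), w = W, h = H))
}

## ---- stump rendering ----

render_one_stump <- function(img, cx, cy, r, target_ratio) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  Y <- matrix(ys, length(ys), length(xs)) - cy
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  d <- sqrt(X^2 + Y^2)
  inside <- d <= r
  n_in <- sum(inside)
  if (n_in == 0L) stop("stump radius too small to rasterize", call. = FALSE)

  lin <- (rep(ys, length(xs)) + (rep(xs, each = length(ys)) - 1L) * H)[inside]
  HW <- H * W

  ## sawn wood surface with growth rings + dark bark rim
  period <- stats::runif(1, 4.5, 9)
  phase <- stats::runif(1, 0, 2 * pi)
  ring <- 0.07 * sin(2 * pi * d[inside] / period + phase)
  base <- c(stats::runif(1, 0.78, 0.88), stats::runif(1, 0.66, 0.76),
            stats::runif(1, 0.48, 0.58))
  noise <- stats::rnorm(n_in, 0, 0.025)
  bark <- d[inside] > 0.9 * r
  Rv <- ifelse(bark, 0.3, base[1] + ring + noise)
  Gv <- ifelse(bark, 0.21, base[2] + ring + noise)
  Bv <- ifelse(bark, 0.13, base[3] + 0.7 * ring + noise)
  bn <- stats::rnorm(n_in, 0, 0.05)
  Rv[bark] <- Rv[bark] + bn[bark]; Gv[bark] <- Gv[bark] + bn[bark]
  Bv[bark] <- Bv[bark] + bn[bark]

  ## rot region: low-potential sub-level set of (distance from a random
  ## interior focus + smooth noise); the threshold is the order statistic at
  ## ceiling(target * n), so the realized pixel ratio lands in
  ## [target, target + 1/n].
  rot <- rep(FALSE, n_in)
  if (target_ratio > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    fx <- cx + stats::runif(1, 0, 0.45 * r) * cos(th)
    fy <- cy + stats::runif(1, 0, 0.45 * r) * sin(th)
    pot <- sqrt((X[inside] + cx - fx)^2 + (Y[inside] + cy - fy)^2) +
      0.5 * r * stats::rnorm(n_in, 0, 0.15) +
      stats::runif(n_in, 0, 1e-6)            # break ties
    k <- min(n_in, max(1L, ceiling(target_ratio * n_in)))
    rot <- pot <= sort(pot, partial = k)[k]
    rn <- stats::rnorm(sum(rot), 0, 0.06)
    Rv[rot] <- clamp(0.42 + 0.25 * ring[rot] + rn)
    Gv[rot] <- clamp(0.33 + 0.2 * ring[rot] + rn)
    Bv[rot] <- clamp(0.26 + 0.15 * ring[rot] + rn * 0.8)
  }

  img[c(lin, lin + HW, lin + 2L * HW)] <- c(clamp(Rv), clamp(Gv), clamp(Bv))

  stump_mask <- matrix(FALSE, H, W); stump_mask[lin] <- TRUE
  rot_mask <- matrix(FALSE, H, W); rot_mask[lin[rot]] <- TRUE
  list(img = img, stump_mask = stump_mask, rot_mask = rot_mask)
}

## Clutter elements covering approximately `frac` of the stump surface.
occlusion_elements <- function(stump_mask, frac) {
  if (frac <= 0) return(list())
  H <- dim(stump_mask)[1]; W <- dim(stump_mask)[2]
  area <- sum(stump_mask)
  on <- which(stump_mask)
  covered <- rep(FALSE, length(on))
  elements <- list()
  for (i in 1:80) {
    p <- on[sample.int(length(on), 1L)]
    cy <- ((p - 1L) %% H) + 1L
    cx <- ((p - 1L) %/% H) + 1L
    e <- clutter_element(cx - 1L, cy - 1L, H, W)
    elements[[length(elements) + 1L]] <- e
    covered <- covered | (on %in% e$lin)
    if (sum(covered) / area >= frac) break
  }
  elements
}

#' Render one labeled synthetic scene
#'
#' Deterministic given `params` (including its seed). Ground-truth masks are
#' captured before lighting, gradient and shadow are applied, so the labels
#' are unaffected by illumination, as manual labels would be.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `"labeled_scene"`: list with `image`
#'   (`H x W x 3` array in `[0,1]`, 8-bit quantized), `stumps` (list of
#'   per-stump records: `stump_mask`, `rot_mask`, `bbox`, `rbr_ratio`,
#'   `rot_class`), and for convenience, when the scene holds exactly one
#'   stump, top-level `stump_mask`, `rot_mask`, `bbox`, `rbr_ratio`,
#'   `rot_class` referring to it.
#' @export
render_scene <- function(params) {
  validate_scene_params(params)
  with_seed(params$seed, render_scene_impl(params))
}

render_scene_impl <- function(p) {
  H <- p$image_height; W <- p$image_width

  ## forest-floor background: brownish base modulated by smooth noise
  n1 <- smooth_noise(H, W, 6); n2 <- smooth_noise(H, W, 16)
  fine <- matrix(stats::rnorm(H * W, 0, 0.03), H, W)
  base_r <- clamp(0.32 + 0.18 * n1 + 0.07 * n2 + fine)
  base_g <- clamp(0.26 + 0.16 * n1 + 0.08 * n2 + fine)
  base_b <- clamp(0.16 + 0.1 * n1 + 0.05 * n2 + fine)
  img <- array(c(base_r, base_g, base_b), dim = c(H, W, 3))

  n_clutter <- round(p$clutter_density * H * W / 1e4)
  img <- paint_elements(img, lapply(seq_len(n_clutter), function(i)
    clutter_element(stats::runif(1, 0, W - 1), stats::runif(1, 0, H - 1), H, W)))

  ## place stumps (non-overlapping discs fully inside the frame)
  stumps <- list()
  placed <- matrix(numeric(0), ncol = 3)   # cx, cy, r
  for (s in seq_len(p$n_stumps)) {
    r <- stats::runif(1, p$stump_radius_range[1], p$stump_radius_range[2]) *
      min(H, W)
    ok <- FALSE
    for (try in 1:50) {
      cx <- stats::runif(1, r + 2, W - r - 3)
      cy <- stats::runif(1, r + 2, H - r - 3)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
              placed[, 3] + r + 4)) { ok <- TRUE; break }
    }
    if (!ok) next   # scene too crowded; skip this stump
    st <- render_one_stump(img, cx, cy, r, p$target_rbr_ratio)
    img <- paint_elements(st$img,
                          occlusion_elements(st$stump_mask, p$occlusion_fraction))
    ratio <- rbr_ratio(st$rot_mask, st$stump_mask)
    stumps[[length(stumps) + 1L]] <- list(
      stump_mask = st$stump_mask, rot_mask = st$rot_mask,
      bbox = bbox_from_mask(st$stump_mask),
      rbr_ratio = ratio, rot_class = class_from_ratio(ratio))
    placed <- rbind(placed, c(cx, cy, r))
  }
  if (p$n_stumps > 0 && length(stumps) == 0L)
    stop("could not place any stump; loosen stump_radius_range", call. = FALSE)

  ## illumination (after mask capture): gain x linear gradient x soft shadow
  g <- stats::runif(1, p$lighting_gain[1], p$lighting_gain[2])
  ang <- stats::runif(1, 0, 2 * pi)
  gx <- cos(ang); gy <- sin(ang)
  proj <- outer(seq(0, 1, length.out = H) * gy, seq(0, 1, length.out = W) * gx, `+`)
  grad <- 1 + 0.15 * (proj - mean(range(proj))) * 2
  light <- g * grad
  if (p$shadow && stats::runif(1) < 0.5) {
    scx <- stats::runif(1, 0, W); scy <- stats::runif(1, 0, H)
    srx <- stats::runif(1, 0.25, 0.6) * W; sry <- stats::runif(1, 0.25, 0.6) * H
    dY <- matrix((seq_len(H) - scy) / sry, H, W)
    dX <- matrix((seq_len(W) - scx) / srx, H, W, byrow = TRUE)
    sd2 <- dX^2 + dY^2
    light <- light * (1 - 0.35 / (1 + exp((sd2 - 1) * 8)))
  }
  img <- img * as.vector(light)   # recycles light across the 3 channels

  scene <- list(image = quantize8(img), stumps = stumps,
                params = p, height = H, width = W)
  if (length(stumps) == 1L)
    scene[c("stump_mask", "rot_mask", "bbox", "rbr_ratio", "rot_class")] <-
      stumps[[1L]][c("stump_mask", "rot_mask", "bbox", "rbr_ratio", "rot_class")]
  class(scene) <- "labeled_scene"
  scene
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene %dx%d, %d stump(s)>\n", x$height, x$width,
              length(x$stumps)))
  for (s in x$stumps)
    cat(sprintf("  rbr_ratio %.3f (%s), bbox [%g,%g)x[%g,%g)\n",
                s$rbr_ratio, as.character(s$rot_class),
                s$bbox[["x_min"]], s$bbox[["x_max"]],
                s$bbox[["y_min"]], s$bbox[["y_max"]]))
  invisible(x)
}

## ---- dataset generation ----

#' Split a total scene count into per-class counts
#'
#' Uses the reference dataset mix 502 : 197 : 301 (no rot : rot < 50% :
#' rot >= 50%) by default, with largest-remainder rounding.
#'
#' @param n_total total number of scenes.
#' @param mix relative class weights in [rot_class_levels()] order.
#' @return named integer vector of per-class counts summing to `n_total`.
#' @export
class_mix_counts <- function(n_total, mix = c(502, 197, 301)) {
  stopifnot(n_total >= 0, length(mix) == 3, all(mix >= 0), sum(mix) > 0)
  raw <- n_total * mix / sum(mix)
  n <- floor(raw)
  rem <- n_total - sum(n)
  if (rem > 0) {
    add <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1
  }
  stats::setNames(as.integer(n), ROT_CLASSES)
}

## Draw a target rot ratio for a class.
draw_target_ratio <- function(cls) {
  switch(cls,
         NO_ROT = 0,
         ROT_LT_50 = stats::runif(1, 0.05, 0.45),
         ROT_GE_50 = stats::runif(1, 0.5, 0.95))
}

#' Generate a set of labeled scenes in memory
#'
#' @param n_per_class integer vector of scene counts in
#'   [rot_class_levels()] order (named or positional).
#' @param params_template [scene_params()] whose per-scene seed and target
#'   ratio are overridden per scene; occlusion is drawn uniformly in
#'   `[0, min(0.3, 3 * occlusion_fraction)]` per scene.
#' @param seed master seed; per-scene seeds are derived from it.
#' @return list of [render_scene()] results, classes grouped in level order.
#' @export
generate_scene_set <- function(n_per_class, params_template = scene_params(),
                               seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  stopifnot(length(n_per_class) == 3L, all(n_per_class >= 0))
  n <- sum(n_per_class)
  seeds <- derive_seeds(seed, n + 1L)
  classes <- rep(ROT_CLASSES, times = n_per_class)
  occ_max <- min(0.3, 3 * params_template$occlusion_fraction)
  lapply(seq_len(n), function(i) {
    p <- params_template
    p$seed <- seeds[i]
    with_seed(seeds[i] %% 100000L + 7L, {
      p$target_rbr_ratio <- draw_target_ratio(classes[i])
      p$occlusion_fraction <- stats::runif(1, 0, occ_max)
    })
    render_scene(p)
  })
}

#' Generate a labeled dataset on disk
#'
#' Writes PNG images, 0/255 PNG masks, a COCO-style JSON annotation index
#' and a flat CSV. Deterministic: the same seed gives byte-identical files.
#'
#' @inheritParams generate_scene_set
#' @param out_dir output directory (created if needed).
#' @return invisibly, the annotation data frame (one row per stump).
#' @export
generate_dataset <- function(n_per_class, params_template = scene_params(),
                             seed = 1L, out_dir) {
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  scenes <- generate_scene_set(n_per_class, params_template, seed)
  write_dataset(scenes, out_dir)
}

write_dataset <- function(scenes, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  images <- list(); annos <- list(); rows <- list(); aid <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    img_file <- sprintf("images/scene_%04d.png", i)
    png::writePNG(sc$image, file.path(out_dir, img_file))
    images[[i]] <- list(id = i, file_name = img_file,
                        height = sc$height, width = sc$width)
    for (j in seq_along(sc$stumps)) {
      st <- sc$stumps[[j]]; aid <- aid + 1L
      sm_file <- sprintf("masks/scene_%04d_stump_%d.png", i, j)
      rm_file <- sprintf("masks/scene_%04d_rot_%d.png", i, j)
      png::writePNG(st$stump_mask * 1, file.path(out_dir, sm_file))
      png::writePNG(st$rot_mask * 1, file.path(out_dir, rm_file))
      b <- st$bbox
      annos[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(as.character(st$rot_class), ROT_CLASSES),
        bbox = c(b[["x_min"]], b[["y_min"]],
                 b[["x_max"]] - b[["x_min"]], b[["y_max"]] - b[["y_min"]]),
        rbr_ratio = st$rbr_ratio,
        stump_mask = sm_file, rot_mask = rm_file)
      rows[[aid]] <- data.frame(
        image = img_file, image_id = i,
        rot_class = as.character(st$rot_class), rbr_ratio = st$rbr_ratio,
        x_min = b[["x_min"]], y_min = b[["y_min"]],
        x_max = b[["x_max"]], y_max = b[["y_max"]],
        stump_mask = sm_file, rot_mask = rm_file)
    }
  }
  coco <- list(
    images = images,
    annotations = annos,
    categories = lapply(seq_along(ROT_CLASSES), function(k)
      list(id = k, name = ROT_CLASSES[k])))
  jsonlite::write_json(coco, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = 10, pretty = FALSE)
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  invisible(df)
}

#' Read a dataset annotation index
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @return data frame with one row per stump annotation (image path, class,
#'   rbr_ratio, box corners, mask paths).
#' @export
read_annotations <- function(dir) {
  f <- file.path(dir, "annotations.csv")
  if (!file.exists(f)) stop("no annotations.csv under ", dir, call. = FALSE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  df$rot_class <- factor(df$rot_class, levels = ROT_CLASSES)
  df
}

#' Load one annotated scene back from disk
#'
#' @param dir dataset directory.
#' @param image_id image id (row of the index).
#' @return a `"labeled_scene"` object (reconstructed from the stored files).
#' @export
load_scene <- function(dir, image_id) {
  df <- read_annotations(dir)
  rows <- df[df$image_id == image_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no such image_id: ", image_id, call. = FALSE)
  img <- png::readPNG(file.path(dir, rows$image[1]))
  stumps <- lapply(seq_len(nrow(rows)), function(j) {
    sm <- png::readPNG(file.path(dir, rows$stump_mask[j])) > 0.5
    rm_ <- png::readPNG(file.path(dir, rows$rot_mask[j])) > 0.5
    ratio <- rows$rbr_ratio[j]
    list(stump_mask = sm, rot_mask = rm_,
         bbox = bbox(rows$x_min[j], rows$y_min[j], rows$x_max[j], rows$y_max[j]),
         rbr_ratio = ratio, rot_class = class_from_ratio(ratio))
  })
  scene <- list(image = img, stumps = stumps,
                height = dim(img)[1], width = dim(img)[2])
  if (length(stumps) == 1L)
    scene[c("stump_mask", "rot_mask", "bbox", "rbr_ratio", "rot_class")] <-
      stumps[[1L]][c("stump_mask", "rot_mask", "bbox", "rbr_ratio", "rot_class")]
  class(scene) <- "labeled_scene"
  scene
}
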