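## Bounding boxes and the segmentation-quality (sq) statistic.
##
## Boxes are axis-aligned pixel rectangles in 0-based, half-open coordinates
## [x_min, x_max) x [y_min, y_max): a box covers the pixel columns
## x_min .. x_max-1 and rows y_min .. y_max-1, so areas and intersections are
## exact integers. x runs along image columns (width), y along rows (height).

#' Create a bounding box
#'
#' @param x_min,y_min,x_max,y_max pixel coordinates, 0-based and half-open:
#'   the box covers columns `[x_min, x_max)` and rows `[y_min, y_max)`.
#' @return an object of class `"bbox"` (named numeric vector).
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b) # 100
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("bbox coordinates must be finite", call. = FALSE)
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"])
    stop("degenerate bbox: need x_min < x_max and y_min < y_max", call. = FALSE)
  class(b) <- "bbox"
  b
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%g,%g) x [%g,%g), area %g>\n",
              x[["x_min"]], x[["x_max"]], x[["y_min"]], x[["y_max"]],
              bbox_area(x)))
  invisible(x)
}

#' Area of a bounding box
#' @param b a [bbox()].
#' @return pixel area (numeric).
#' @export
bbox_area <- function(b) {
  (b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]])
}

#' Intersection area of two bounding boxes
#'
#' Half-open boxes: touching edges do not overlap.
#'
#' @param a,b [bbox()] objects.
#' @return intersection area in pixels; 0 when disjoint.
#' @examples
#' intersect_area(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10)) # 50
#' @export
intersect_area <- function(a, b) {
  w <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  h <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Tight bounding box of a binary mask
#'
#' @param mask logical (or 0/1) matrix, rows = image rows (y), columns = x.
#' @return the tight [bbox()] around the `TRUE` pixels (0-based, half-open).
#' @export
bbox_from_mask <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  bbox(x_min = min(idx[, 2]) - 1L, y_min = min(idx[, 1]) - 1L,
       x_max = max(idx[, 2]), y_max = max(idx[, 1]))
}

region_area <- function(r) {
  if (inherits(r, "bbox")) bbox_area(r)
  else sum(r != 0)
}

region_overlap <- function(a, b) {
  if (inherits(a, "bbox") && inherits(b, "bbox")) return(intersect_area(a, b))
  if (inherits(a, "bbox") || inherits(b, "bbox"))
    stop("mix of bbox and mask regions is not supported; rasterize the box first",
         call. = FALSE)
  if (!identical(dim(a), dim(b)))
    stop("masks must share dimensions", call. = FALSE)
  sum(a != 0 & b != 0)
}

#' Segmentation quality (sq) of a segmented region against a labeled region
#'
#' Segmentation-overlap is the fraction of the manually labeled region L that
#' the segmented region S covers, O/L, where O is the overlap area.
#' Segmentation-efficiency is the fraction of the segmented region that lies
#' on the labeled object, O/S. Their average,
#' \deqn{sq = \frac{O/L + O/S}{2},}
#' lies in `[0, 1]` and equals 1 exactly when S and L coincide. Note sq is
#' deliberately not intersection-over-union.
#'
#' @param segmented,labeled regions: either [bbox()] objects or binary masks
#'   of identical dimensions. Both must be non-empty.
#' @return an object of class `"sq_result"`: list with `overlap_area`,
#'   `labeled_area`, `segmented_area`, `segmentation_overlap`,
#'   `segmentation_efficiency` and `sq`.
#' @examples
#' sq_score(bbox(0, 5, 10, 15), bbox(0, 0, 10, 10))$sq   # 0.5
#' sq_score(bbox(0, 0, 5, 5), bbox(0, 0, 10, 10))$sq     # 0.625
#' @export
sq_score <- function(segmented, labeled) {
  S <- region_area(segmented)
  L <- region_area(labeled)
  if (S <= 0 || L <= 0)
    stop("sq_score: both regions must be non-empty", call. = FALSE)
  O <- region_overlap(segmented, labeled)
  res <- list(overlap_area = O, labeled_area = L, segmented_area = S,
              segmentation_overlap = O / L,
              segmentation_efficiency = O / S,
              sq = (O / L + O / S) / 2)
  class(res) <- "sq_result"
  res
}

#' @export
print.sq_result <- function(x, ...) {
  cat(sprintf("<sq %.4f  (overlap O/L %.4f, efficiency O/S %.4f; O=%g L=%g S=%g)>\n",
              x$sq, x$segmentation_overlap, x$segmentation_efficiency,
              x$overlap_area, x$labeled_area, x$segmented_area))
  invisible(x)
}

## Fast sq between one box and many boxes given as a 4-column matrix
## (x_min, y_min, x_max, y_max); used by NMS and detection matching.
sq_vec <- function(b, boxes) {
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nrow = 1L)
  w <- pmin(b[["x_max"]], boxes[, 3]) - pmax(b[["x_min"]], boxes[, 1])
  h <- pmin(b[["y_max"]], boxes[, 4]) - pmax(b[["y_min"]], boxes[, 2])
  O <- pmax(w, 0) * pmax(h, 0)
  L <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  S <- bbox_area(b)
  (O / L + O / S) / 2
}
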