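## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of per-item seeds from a master seed, all < 2^31.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

## Clamp numeric values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

## Quantise a [0,1] image array to 8-bit levels (k/255) so that in-memory
## pixels equal their PNG round-trip exactly.
quantize8 <- function(img) round(clamp(img) * 255) / 255

## stumpRBR images are H x W x 3 arrays in [0,1]; EBImage stores x (width)
## first. These two helpers convert.
as_ebimage <- function(img) {
  if (length(dim(img)) == 2L)
    EBImage::Image(t(img))
  else
    EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
}

from_ebimage <- function(e) {
  d <- EBImage::imageData(e)
  if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
}

#' Resize an image array
#'
#' Bilinear resize (with antialiasing) of an `H x W x 3` (or `H x W`) array
#' in `[0,1]` to `h` rows by `w` columns, via [EBImage::resize()].
#'
#' @param img numeric array, `H x W x 3` or `H x W`, values in `[0,1]`.
#' @param h,w target numbers of rows and columns.
#' @return resized array with values clamped to `[0,1]`.
#' @export
resize_image <- function(img, h, w) {
  stopifnot(h >= 1, w >= 1)
  d <- dim(img)
  if (d[1] == h && d[2] == w) return(img)
  out <- from_ebimage(EBImage::resize(as_ebimage(img), w = w, h = h))
  clamp(out)
}

## Convert an RGB array to grayscale (channel mean).
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
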