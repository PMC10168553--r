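#' 2D MR-like image
#'
#' A scalar field on an H x W pixel grid with physical pixel spacing.
#' Intensities live in `[0, 1]`; spacing defaults to a 50 x 50 cm field of
#' view divided by the grid size, so distances downstream are in mm.
#'
#' @param pixels numeric H x W matrix with finite values in `[0, 1]`.
#' @param spacing_mm numeric length-2 (row, col) pixel size in mm.
#' @return an `Image2D` object.
#' @export
Image2D <- function(pixels, spacing_mm = 500 / dim(pixels)) {
  pixels <- as.matrix(pixels)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  obj <- structure(list(pixels = pixels, spacing_mm = spacing_mm),
                   class = "Image2D")
  validate_image2d(obj)
  obj
}

validate_image2d <- function(x) {
  p <- x$pixels
  if (nrow(p) < 32L || ncol(p) < 32L)
    stop("Image2D must be at least 32 x 32")
  if (!all(is.finite(p)))
    stop("Image2D intensities must be finite")
  if (min(p) < 0 || max(p) > 1)
    stop("Image2D intensities must lie in [0, 1]")
  if (any(x$spacing_mm <= 0))
    stop("Image2D spacing must be positive")
  invisible(x)
}

#' Binary lung parenchyma mask
#'
#' Same grid and spacing as its image; typically two foreground components
#' (left and right lung). Foreground never touches the image border.
#'
#' @param pixels integer/logical H x W matrix of 0/1.
#' @param spacing_mm numeric length-2 (row, col) pixel size in mm.
#' @return a `LungMask` object.
#' @export
LungMask <- function(pixels, spacing_mm = 500 / dim(pixels)) {
  pixels <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  obj <- structure(list(pixels = pixels,
                        spacing_mm = rep_len(as.numeric(spacing_mm), 2L)),
                   class = "LungMask")
  validate_lungmask(obj)
  obj
}

validate_lungmask <- function(x, require_nonempty = FALSE) {
  p <- x$pixels
  if (!all(p %in% c(0L, 1L))) stop("LungMask values must be 0/1")
  if (require_nonempty && sum(p) == 0L) stop("LungMask is empty")
  border <- c(p[1, ], p[nrow(p), ], p[, 1], p[, ncol(p)])
  if (any(border != 0L)) stop("LungMask foreground touches the image border")
  invisible(x)
}

#' Two-class contour ground truth
#'
#' Binary band of nominal width `width_px` tracing the inner margin of a
#' lung mask. The positive class for contour-CNN training; background is
#' everything else, outside and inside the lung alike.
#'
#' @param pixels integer/logical H x W matrix of 0/1.
#' @param width_px nominal band width in pixels.
#' @return a `ContourLabel` object.
#' @export
ContourLabel <- function(pixels, width_px = 6L) {
  pixels <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  if (width_px < 1L) stop("width_px must be >= 1")
  structure(list(pixels = pixels, width_px = as.integer(width_px)),
            class = "ContourLabel")
}

#' Per-pixel contour-class probability map
#'
#' @param pixels numeric H x W matrix with values in `[0, 1]`.
#' @return a `ProbabilityMap` object.
#' @export
ProbabilityMap <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop("ProbabilityMap values must be finite and in [0, 1]")
  structure(list(pixels = pixels), class = "ProbabilityMap")
}

#' @export
print.Image2D <- function(x, ...) {
  cat(sprintf("<Image2D %d x %d, spacing %.2f x %.2f mm, range [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.LungMask <- function(x, ...) {
  cat(sprintf("<LungMask %d x %d, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
print.ContourLabel <- function(x, ...) {
  cat(sprintf("<ContourLabel %d x %d, width %d px, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), x$width_px, sum(x$pixels)))
  invisible(x)
}

#' @export
print.ProbabilityMap <- function(x, ...) {
  cat(sprintf("<ProbabilityMap %d x %d, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

# accept either a wrapped object or a bare matrix
as_pixels <- function(x) {
  if (is.matrix(x)) x else x$pixels
}
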