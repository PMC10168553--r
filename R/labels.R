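#' Build the two-class contour ground truth from a lung mask
#'
#' The marginal pixels of the mask (band of nominal width `width_px`,
#' default 6) form a closed lung contour: the mask minus the mask eroded
#' `width_px` times with the 8-connected (3 x 3 box) structuring element.
#' The band is inner — every contour pixel is a mask pixel — and for mask
#' components thicker than twice the width it forms a single closed ring
#' whose flood fill recovers the component exactly.
#'
#' @param mask a [LungMask] or binary matrix.
#' @param width_px band width in pixels (>= 1).
#' @return a [ContourLabel].
#' @export
make_contour_label <- function(mask, width_px = 6L) {
  if (width_px < 1L) stop("width_px must be >= 1")
  m <- as_pixels(mask)
  if (sum(m) == 0L) return(ContourLabel(matrix(0L, nrow(m), ncol(m)), width_px))
  # erosion width_px times by the 3x3 box == one erosion by a
  # (2*width_px + 1) square (Chebyshev-distance band)
  brush <- matrix(1L, 2L * width_px + 1L, 2L * width_px + 1L)
  eroded <- as.matrix(EBImage::erode(m, brush))
  ContourLabel(m == 1L & eroded == 0L, width_px)
}

#' Convert a contour label to a per-pixel class map
#'
#' Class 0 is background (outside and inside the lung), class 1 is the
#' lung contour. The mapping is the identity on the binary band, so the
#' round trip through [classmap_to_label()] is exact.
#'
#' @param label a [ContourLabel].
#' @return integer matrix of classes in `{0, 1}`.
#' @export
label_to_classmap <- function(label) {
  p <- as_pixels(label)
  matrix(as.integer(p != 0), nrow(p), ncol(p))
}

#' Inverse of [label_to_classmap()]
#'
#' @param classmap integer matrix in `{0, 1}`.
#' @param width_px nominal band width recorded on the label.
#' @return a [ContourLabel].
#' @export
classmap_to_label <- function(classmap, width_px = 6L) {
  if (!all(classmap %in% c(0L, 1L))) stop("classmap values must be 0/1")
  ContourLabel(classmap, width_px)
}
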