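#' Postprocessing parameters
#'
#' @param threshold probability cutoff for the contour class. The
#'   default 6e-4 (0.06%) reflects an empirically determined operating
#'   point for a well-converged contour network; see
#'   [calibrate_threshold()] for choosing it on validation data.
#' @param closing_radius_px radius of the morphological closing element
#'   bridging small contour gaps before filling (0 disables closing).
#' @param min_component_px contour components smaller than this are
#'   discarded before filling (0 keeps all).
#' @param keep_components maximum number of lung components kept in the
#'   filled mask (default 2: left and right lung).
#' @return a `PostprocessParams` object.
#' @export
postprocess_params <- function(threshold = 6e-4, closing_radius_px = 2L,
                               min_component_px = 0L, keep_components = 2L) {
  p <- structure(list(threshold = threshold,
                      closing_radius_px = as.integer(closing_radius_px),
                      min_component_px = as.integer(min_component_px),
                      keep_components = as.integer(keep_components)),
                 class = "PostprocessParams")
  if (p$threshold <= 0 || p$threshold >= 1) stop("threshold must be in (0, 1)")
  if (p$closing_radius_px < 0L || p$min_component_px < 0L)
    stop("radii must be >= 0")
  p
}

#' Label 8-connected foreground components
#'
#' @param mask binary matrix (or [LungMask]).
#' @return integer matrix of component labels (0 = background).
#' @export
label8_components <- function(mask) {
  m <- as_pixels(mask)
  label8_cpp(matrix(as.integer(m != 0), nrow(m), ncol(m)))
}

#' Threshold a contour probability map
#'
#' A pixel joins the contour iff its probability is at least the
#' threshold. A morphological closing (disc of the configured radius)
#' then bridges small gaps, and components below the minimum size are
#' removed.
#'
#' @param prob a [ProbabilityMap] or numeric matrix.
#' @param params a [postprocess_params()].
#' @return integer 0/1 contour matrix.
#' @export
threshold_contour <- function(prob, params = postprocess_params()) {
  p <- as_pixels(prob)
  bw <- matrix(as.integer(p >= params$threshold), nrow(p), ncol(p))
  if (params$closing_radius_px > 0L && any(bw == 1L)) {
    brush <- EBImage::makeBrush(2L * params$closing_radius_px + 1L, "disc")
    bw <- matrix(as.integer(as.matrix(EBImage::closing(bw, brush)) != 0),
                 nrow(p), ncol(p))
  }
  if (params$min_component_px > 0L && any(bw == 1L)) {
    lab <- label8_cpp(bw)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_component_px)
    if (length(drop)) bw[lab %in% drop] <- 0L
  }
  bw
}

#' Fill a closed contour to recover the parenchyma mask
#'
#' The background is flood filled from the image border (4-connected
#' through non-contour pixels); everything not reached and not already
#' contour becomes interior, and the mask is the union of contour and
#' interior. At most `keep_components` largest 8-connected components
#' are retained. An unclosed contour encloses no interior and is left
#' as-is — such cases are reported in the `"closure_failed"` attribute.
#'
#' @param contour integer 0/1 matrix from [threshold_contour()].
#' @param params a [postprocess_params()].
#' @param spacing_mm pixel spacing recorded on the returned mask.
#' @return a [LungMask]; attribute `"closure_failed"` is `TRUE` when no
#'   interior pixel was recovered from a non-empty contour.
#' @export
fill_contour <- function(contour, params = postprocess_params(),
                         spacing_mm = 500 / dim(contour)) {
  ct <- as_pixels(contour)
  reached <- flood_border_cpp(matrix(as.integer(ct != 0), nrow(ct), ncol(ct)))
  interior <- reached == 0L & ct == 0L
  mask <- matrix(as.integer(ct != 0 | interior), nrow(ct), ncol(ct))
  if (params$keep_components > 0L && any(mask == 1L)) {
    lab <- label8_cpp(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(params$keep_components,
                                                        length(sizes)))]
    mask[!(lab %in% keep)] <- 0L
  }
  # a mask touching the border cannot be a valid lung mask; trim it so the
  # object remains well-formed and scoring still works
  mask[c(1L, nrow(mask)), ] <- 0L
  mask[, c(1L, ncol(mask))] <- 0L
  out <- LungMask(mask, spacing_mm)
  attr(out, "closure_failed") <- sum(ct) > 0L && !any(interior)
  out
}

#' Postprocess a probability map into a lung mask
#'
#' Convenience composition of [threshold_contour()] and
#' [fill_contour()].
#'
#' @param prob a [ProbabilityMap] or matrix.
#' @param params a [postprocess_params()].
#' @param spacing_mm pixel spacing of the returned mask.
#' @return a [LungMask].
#' @export
postprocess_probability <- function(prob, params = postprocess_params(),
                                    spacing_mm = 500 / dim(as_pixels(prob))) {
  fill_contour(threshold_contour(prob, params), params, spacing_mm)
}

#' Choose the contour threshold on validation data
#'
#' The operating threshold of the contour network is an empirical
#' quantity: it must be low enough to close the predicted contour and
#' high enough not to flood the background. This helper evaluates a
#' grid of candidate thresholds on validation records (predict,
#' postprocess, score against the reference masks) and returns the
#' threshold with the highest mean Sorensen-Dice coefficient.
#'
#' @param model a trained `unet_model`.
#' @param records validation records with `image` and `mask` (or
#'   `label`, whose fill is then used as reference).
#' @param grid candidate thresholds.
#' @param params a [postprocess_params()] whose other fields are reused.
#' @return the selected threshold; attribute `"scores"` holds the grid
#'   and mean SDC values.
#' @export
calibrate_threshold <- function(model, records,
                                grid = c(6e-4, 3e-3, 0.01, 0.05, 0.2, 0.5),
                                params = postprocess_params()) {
  probs <- predict_records(model, records)
  refs <- lapply(records, function(r) {
    if (!is.null(r$mask)) as_pixels(r$mask)
    else as_pixels(fill_contour(as_pixels(r$label), params))
  })
  mean_sdc <- vapply(grid, function(th) {
    pp <- params; pp$threshold <- th
    mean(vapply(seq_along(records), function(i) {
      m <- fill_contour(threshold_contour(probs[[i]], pp), pp)
      sdc(m$pixels, refs[[i]])
    }, 0))
  }, 0)
  best <- grid[which.max(mean_sdc)]
  attr(best, "scores") <- data.frame(threshold = grid, mean_sdc = mean_sdc)
  best
}
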