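#' Parameters of artificial consolidation synthesis
#'
#' Controls the model-based synthesis of parenchymal consolidations:
#' a randomly placed region inside one lung is filled with uniform noise
#' spanning that lung's intensity range, the whole image is median
#' filtered (10 x 10), the filtered result is composited back inside the
#' lung only, and a small Gaussian blur blends the region border.
#'
#' @param area_fraction_range `(lo, hi)` target region area as a fraction
#'   of the host lung's area, `0 < lo <= hi < 1`.
#' @param border_placement place the region on the lung boundary (the
#'   peripheral-consolidation setting used for training data).
#' @param median_kernel length-2 median filter window in pixels.
#' @param gaussian_kernel length-2 Gaussian kernel size in pixels.
#' @param gaussian_sigma Gaussian standard deviation in pixels.
#' @param blend_band_px half-width of the blend band around the region
#'   boundary, in pixels.
#' @return a `ConsolidationParams` object.
#' @export
consolidation_params <- function(area_fraction_range = c(0.05, 0.35),
                                 border_placement = TRUE,
                                 median_kernel = c(10L, 10L),
                                 gaussian_kernel = c(5L, 5L),
                                 gaussian_sigma = 1.0,
                                 blend_band_px = 2L) {
  p <- structure(list(area_fraction_range = as.numeric(area_fraction_range),
                      border_placement = isTRUE(border_placement),
                      median_kernel = as.integer(median_kernel),
                      gaussian_kernel = as.integer(gaussian_kernel),
                      gaussian_sigma = as.numeric(gaussian_sigma),
                      blend_band_px = as.integer(blend_band_px)),
                 class = "ConsolidationParams")
  a <- p$area_fraction_range
  if (length(a) != 2L || a[1] <= 0 || a[1] > a[2] || a[2] >= 1)
    stop("area_fraction_range must satisfy 0 < lo <= hi < 1")
  if (any(p$median_kernel < 1L) || any(p$gaussian_kernel < 1L))
    stop("kernel sizes must be >= 1")
  if (p$gaussian_sigma <= 0) stop("gaussian_sigma must be > 0")
  p
}

#' Sample a consolidation region inside one lung
#'
#' Picks one lung component at random, samples a target area fraction,
#' and grows a connected irregular region by priority flooding a smoothed
#' random field from a seed pixel. With `border_placement` the seed lies
#' on the lung's inner boundary, so the region touches the lung margin
#' (peripheral consolidation); the grown region has exactly the target
#' area whenever the lung can host it.
#'
#' @param mask a [LungMask] with at least one component.
#' @param params a [consolidation_params()].
#' @param seed RNG seed.
#' @return integer 0/1 matrix marking the region, with attributes
#'   `"lung_component"` (label id) and `"target_area"`; `NULL` if the
#'   host lung is too small to host the minimum area.
#' @export
sample_region <- function(mask, params = consolidation_params(), seed = 1L) {
  m <- as_pixels(mask)
  lab <- label8_cpp(m)
  ncomp <- max(lab)
  if (ncomp < 1L) stop("mask has no foreground component")
  with_seed(seed, {
    comp_id <- sample.int(ncomp, 1L)
    comp <- matrix(as.integer(lab == comp_id), nrow(m), ncol(m))
    lung_area <- sum(comp)
    frac <- runif(1, params$area_fraction_range[1], params$area_fraction_range[2])
    target <- round(frac * lung_area)
    if (target < 1L || target > lung_area) NULL else {
      # irregular blob shapes: smoothed white noise as the growth potential
      field <- matrix(rnorm(length(m)), nrow(m), ncol(m))
      field <- as.matrix(EBImage::gblur(field, sigma = max(1.5, nrow(m) / 32)))
      if (params$border_placement) {
        inner <- as.matrix(EBImage::erode(comp, matrix(1L, 3L, 3L)))
        boundary <- which(comp == 1L & inner == 0L)
        seed_px <- boundary[sample.int(length(boundary), 1L)]
      } else {
        seed_px <- which(comp == 1L)[sample.int(lung_area, 1L)]
      }
      sr <- (seed_px - 1L) %% nrow(m)
      sc <- (seed_px - 1L) %/% nrow(m)
      region <- region_grow_cpp(field, comp, sr, sc, as.integer(target))
      attr(region, "lung_component") <- comp_id
      attr(region, "target_area") <- as.integer(target)
      region
    }
  })
}

#' Fill a region with uniform draws spanning the host lung's range
#'
#' Step two of consolidation synthesis in isolation: region pixels are
#' replaced by i.i.d. Uniform(min, max) draws, where min and max are the
#' intensity extremes of the selected lung component in the input image.
#'
#' @param image an [Image2D] or matrix.
#' @param lung_component 0/1 matrix of the host lung component.
#' @param region 0/1 matrix, subset of `lung_component`.
#' @param seed RNG seed.
#' @return numeric matrix with the filled region.
#' @export
fill_region_uniform <- function(image, lung_component, region, seed = 1L) {
  img <- as_pixels(image)
  comp <- as_pixels(lung_component)
  reg <- region != 0
  if (any(reg & comp == 0)) stop("region must lie inside the lung component")
  lo <- min(img[comp == 1]); hi <- max(img[comp == 1])
  with_seed(seed, {
    img[reg] <- runif(sum(reg), lo, hi)
    img
  })
}

gaussian_kernel_2d <- function(size, sigma) {
  half_r <- (size[1] - 1) / 2; half_c <- (size[2] - 1) / 2
  r <- seq(-half_r, half_r); cc <- seq(-half_c, half_c)
  k <- outer(exp(-r^2 / (2 * sigma^2)), exp(-cc^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Insert an artificial consolidation into a lung image
#'
#' Four steps: (1) the given region of one lung is filled with uniform
#' random intensities between the minimum and maximum of the selected
#' lung; (2) a 10 x 10 median filter is applied to the whole image;
#' (3) the filtered image is kept inside the lung only — every non-lung
#' pixel of the output equals the input exactly; (4) a 5 x 5 Gaussian
#' blur is applied on a narrow band around the region boundary (clipped
#' to the lung) to blend the consolidation into the parenchyma.
#' Ground-truth labels are untouched by construction.
#'
#' @param image an [Image2D].
#' @param mask the matching [LungMask].
#' @param region 0/1 matrix from [sample_region()].
#' @param params a [consolidation_params()].
#' @param seed RNG seed for the uniform fill.
#' @return an [Image2D] with the consolidation inserted.
#' @export
insert_consolidation <- function(image, mask, region,
                                 params = consolidation_params(), seed = 1L) {
  img <- as_pixels(image)
  m <- as_pixels(mask)
  reg <- region != 0
  if (any(reg & m == 0)) stop("region must be a subset of the lung mask")
  spacing <- if (inherits(image, "Image2D")) image$spacing_mm else 500 / dim(img)
  if (!any(reg)) return(Image2D(img, spacing))
  lab <- label8_cpp(m)
  comp_ids <- unique(lab[reg])
  if (length(comp_ids) != 1L)
    stop("region must lie inside exactly one lung component")
  comp <- matrix(as.integer(lab == comp_ids), nrow(m), ncol(m))
  filled <- fill_region_uniform(img, comp, reg, seed = seed)
  med <- median_filter_cpp(filled, params$median_kernel[1], params$median_kernel[2])
  out <- img
  out[m == 1] <- med[m == 1]
  # blend band: region boundary dilated by blend_band_px, inside the lung
  regi <- matrix(as.integer(reg), nrow(m), ncol(m))
  inner <- as.matrix(EBImage::erode(regi, matrix(1L, 3L, 3L)))
  boundary <- regi == 1L & inner == 0L
  band <- as.matrix(EBImage::dilate(
    matrix(as.integer(boundary), nrow(m), ncol(m)),
    matrix(1L, 2L * params$blend_band_px + 1L, 2L * params$blend_band_px + 1L)
  )) == 1 & m == 1
  if (any(band)) {
    kern <- gaussian_kernel_2d(params$gaussian_kernel, params$gaussian_sigma)
    blurred <- filter_kernel_cpp(out, kern)
    out[band] <- blurred[band]
  }
  Image2D(clip01(out), spacing)
}

#' Insert consolidations into every record of a dataset
#'
#' Applies [sample_region()] and [insert_consolidation()] to each record,
#' leaving labels and masks unchanged: the network must learn to include
#' consolidations inside the lung contour. Records whose lungs cannot
#' host the minimum area are kept unmodified and counted.
#'
#' @param records list of records with elements `image`, `mask` and
#'   optionally `label`.
#' @param params a [consolidation_params()].
#' @param seed stream seed; per-record seeds are derived from it.
#' @return records with consolidated images; each record gains a
#'   `region` element, and the attribute `"consolidation_log"` is a
#'   `data.frame` (id, consolidated, lung_component, area).
#' @export
consolidate_dataset <- function(records, params = consolidation_params(),
                                seed = 1L) {
  log <- data.frame(id = character(0), consolidated = logical(0),
                    lung_component = integer(0), area = integer(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    rseed <- derive_seed(seed, "consolidation", i)
    region <- if (is.null(rec$mask) || sum(as_pixels(rec$mask)) == 0L) NULL
              else sample_region(rec$mask, params, seed = rseed)
    if (is.null(region)) {
      log <- rbind(log, data.frame(id = rec$id %||% as.character(i),
                                   consolidated = FALSE,
                                   lung_component = NA_integer_,
                                   area = NA_integer_))
      next
    }
    rec$image <- insert_consolidation(rec$image, rec$mask, region, params,
                                      seed = derive_seed(rseed, "fill"))
    rec$region <- region
    records[[i]] <- rec
    log <- rbind(log, data.frame(id = rec$id %||% as.character(i),
                                 consolidated = TRUE,
                                 lung_component = attr(region, "lung_component"),
                                 area = sum(region)))
  }
  attr(records, "consolidation_log") <- log
  records
}
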