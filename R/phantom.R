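#' Phantom specification
#'
#' Parameters of one synthetic coronal lung-MR-like slice. The phantom
#' emulates a temporally-averaged 2D coronal slice: two low-intensity lung
#' fields inside a brighter thorax, with a slice-position parameter (slices
#' far from the central, tracheal slice show smaller lung fields) and two
#' sequence intensity profiles (`FLASH`: moderate body/lung contrast;
#' `bSSFP`: higher contrast with mild horizontal banding).
#'
#' @param matrix_size grid side in pixels (>= 32); the pixel spacing is
#'   `500 / matrix_size` mm per axis (50 x 50 cm field of view).
#' @param slice_offset_mm signed distance from the central slice in mm,
#'   `|offset| <= 80`; lung area shrinks as `|offset|` grows.
#' @param sequence_kind `"FLASH"` or `"bSSFP"`.
#' @param lung_scale relative lung size in `(0, 1]`.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed controlling the anatomical deformation and noise.
#' @return a `PhantomSpec` object.
#' @export
phantom_spec <- function(matrix_size = 64L, slice_offset_mm = 0,
                         sequence_kind = c("FLASH", "bSSFP"),
                         lung_scale = 0.85, noise_sd = 0.02, seed = 1L) {
  sequence_kind <- match.arg(sequence_kind)
  spec <- structure(list(matrix_size = as.integer(matrix_size),
                         slice_offset_mm = as.numeric(slice_offset_mm),
                         sequence_kind = sequence_kind,
                         lung_scale = as.numeric(lung_scale),
                         noise_sd = as.numeric(noise_sd),
                         seed = as.integer(seed)),
                    class = "PhantomSpec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$matrix_size < 32L) stop("matrix_size must be >= 32")
  if (abs(spec$slice_offset_mm) > 80) stop("|slice_offset_mm| must be <= 80")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$lung_scale <= 0 || spec$lung_scale > 1)
    stop("lung_scale must be in (0, 1]")
  invisible(spec)
}

# lung-size factor: strictly decreasing in |offset|, mimicking anterior and
# posterior coronal slices cutting smaller lung cross sections
offset_shrink <- function(offset_mm) {
  1 - 0.55 * (abs(offset_mm) / 80)^1.2
}

#' Generate one synthetic lung phantom
#'
#' Renders an MR-like slice and its ground-truth lung mask. The two lungs
#' are mirrored super-ellipses, warped by a smooth random radial
#' deformation and cut below by a sine-arc diaphragm dome; the thorax is a
#' brighter ellipse on a dark background. The construction guarantees mean
#' lung intensity below mean non-lung intensity (for moderate noise), a
#' mask of exactly two 8-connected components away from extreme slice
#' offsets, no mask foreground on the border, and bit-identical output for
#' a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([Image2D]) and `mask` ([LungMask]).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "PhantomSpec")) stop("spec must be a PhantomSpec")
  validate_phantom_spec(spec)
  n <- spec$matrix_size
  spacing <- rep(500 / n, 2L)
  with_seed(spec$seed, {
    u <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)   # col coord
    v <- matrix(rep(seq(-1, 1, length.out = n), times = n), n, n)  # row coord

    # thorax ellipse, mildly randomized
    ta <- 0.86 + runif(1, -0.03, 0.03)
    tb <- 0.92 + runif(1, -0.02, 0.02)
    body <- (u / ta)^2 + ((v - 0.02) / tb)^2 <= 1

    s <- spec$lung_scale * offset_shrink(spec$slice_offset_mm)
    mask <- matrix(0L, n, n)
    for (side in c(-1, 1)) {
      u0 <- side * (0.40 + runif(1, -0.02, 0.02))
      v0 <- -0.10 + runif(1, -0.03, 0.03)
      a <- 0.27 * s / 0.85
      b <- 0.52 * s / 0.85
      p <- 2.5
      rho <- (abs((u - u0) / a)^p + abs((v - v0) / b)^p)^(1 / p)
      theta <- atan2(v - v0, u - u0)
      ck <- runif(3, -0.035, 0.035)
      ph <- runif(3, 0, 2 * pi)
      rmod <- 1 + ck[1] * cos(theta + ph[1]) + ck[2] * cos(2 * theta + ph[2]) +
        ck[3] * cos(3 * theta + ph[3])
      lung <- rho <= rmod
      # diaphragm: remove lung below a cosine dome
      vd <- 0.30 + runif(1, -0.04, 0.04)
      h <- 0.10 + runif(1, -0.03, 0.03)
      vcut <- vd - h * cos(pmin(pi / 2, abs(u - u0) / (1.15 * a) * (pi / 2)))
      lung <- lung & (v <= vcut) & body
      mask[lung] <- 1L
    }
    # keep lungs off the border regardless of deformation draw
    mask[c(1L, 2L, n - 1L, n), ] <- 0L
    mask[, c(1L, 2L, n - 1L, n)] <- 0L

    if (spec$sequence_kind == "bSSFP") {
      bg_i <- 0.05; body_i <- 0.72; lung_i <- 0.10
    } else {
      bg_i <- 0.06; body_i <- 0.55; lung_i <- 0.20
    }
    img <- matrix(bg_i, n, n)
    img[body] <- body_i
    # smooth mediastinal/apical shading
    g1 <- runif(1, -0.06, 0.06); g2 <- runif(1, -0.06, 0.06)
    img[body] <- img[body] + g1 * u[body] + g2 * v[body]
    img[mask == 1L] <- lung_i + 0.03 * (v[mask == 1L] + 1) / 2
    if (spec$sequence_kind == "bSSFP") {
      band <- 1 + 0.05 * sin(2 * pi * 3 * (v + 1) / 2 + runif(1, 0, 2 * pi))
      img <- img * ifelse(body, band, 1)
    }
    # soften boundaries as temporal averaging does
    img <- as.matrix(EBImage::gblur(img, sigma = max(0.7, n / 128)))
    if (spec$noise_sd > 0)
      img <- img + rnorm(n * n, sd = spec$noise_sd)
    img <- clip01(img)
    list(image = Image2D(img, spacing), mask = LungMask(mask, spacing))
  })
}

#' Generate a cohort of phantoms with category metadata
#'
#' Samples `n` phantom specs from the given ranges, renders them and
#' returns a manifest of records carrying the category-determining
#' metadata (sequence kind and slice offset). The number of
#' anterior/posterior records (`|offset| >= 17` mm) is allocated
#' deterministically as `round(ap_fraction * n)`, and likewise the number
#' of bSSFP records, so requested fractions are met within `1/n`.
#'
#' @param n number of phantoms (>= 1).
#' @param spec_ranges list of sampling ranges; recognised elements
#'   `matrix_size`, `ap_fraction`, `bssfp_fraction`, `offset_ap_mm`
#'   (length-2), `offset_central_mm` (length-2), `lung_scale` (length-2),
#'   `noise_sd` (length-2). Missing elements use defaults.
#' @param seed cohort seed.
#' @return list of records, each with elements `id`, `image`, `mask`,
#'   `sequence_kind`, `slice_offset_mm`; the attribute `"meta"` holds a
#'   summary `data.frame`.
#' @export
generate_cohort <- function(n, spec_ranges = list(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  r <- utils::modifyList(list(
    matrix_size = 64L, ap_fraction = 0.2, bssfp_fraction = 0.5,
    offset_ap_mm = c(17, 60), offset_central_mm = c(0, 16.5),
    lung_scale = c(0.75, 0.95), noise_sd = c(0.01, 0.04)
  ), spec_ranges)
  for (nm in c("offset_ap_mm", "offset_central_mm", "lung_scale", "noise_sd"))
    if (length(r[[nm]]) != 2L || r[[nm]][1] > r[[nm]][2])
      stop("range '", nm, "' must be a non-empty interval")
  with_seed(seed, {
    n_ap <- round(r$ap_fraction * n)
    n_bssfp <- round(r$bssfp_fraction * n)
    ap <- logical(n); ap[sample.int(n, n_ap)] <- TRUE
    bssfp <- logical(n); bssfp[sample.int(n, n_bssfp)] <- TRUE
    offs <- ifelse(ap,
                   runif(n, r$offset_ap_mm[1], r$offset_ap_mm[2]) *
                     sample(c(-1, 1), n, replace = TRUE),
                   runif(n, r$offset_central_mm[1], r$offset_central_mm[2]) *
                     sample(c(-1, 1), n, replace = TRUE))
    scales <- runif(n, r$lung_scale[1], r$lung_scale[2])
    noises <- runif(n, r$noise_sd[1], r$noise_sd[2])
    seeds <- vapply(seq_len(n), function(i) derive_seed(seed, "phantom", i),
                    integer(1))
    records <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- phantom_spec(matrix_size = r$matrix_size,
                           slice_offset_mm = offs[i],
                           sequence_kind = if (bssfp[i]) "bSSFP" else "FLASH",
                           lung_scale = scales[i], noise_sd = noises[i],
                           seed = seeds[i])
      ph <- generate_phantom(spec)
      records[[i]] <- list(id = sprintf("ph%04d", i),
                           image = ph$image, mask = ph$mask,
                           sequence_kind = spec$sequence_kind,
                           slice_offset_mm = spec$slice_offset_mm)
    }
    meta <- data.frame(
      id = vapply(records, `[[`, "", "id"),
      sequence_kind = vapply(records, `[[`, "", "sequence_kind"),
      slice_offset_mm = vapply(records, `[[`, 0, "slice_offset_mm"),
      stringsAsFactors = FALSE
    )
    attr(records, "meta") <- meta
    records
  })
}
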