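#' Assign a slice to its sequence/position category
#'
#' Coronal slices far from the central (tracheal) slice are
#' underrepresented in typical databases; slices with
#' `|offset| >= ap_threshold_mm` form the anterior/posterior (AP)
#' variants of each sequence family.
#'
#' @param sequence_kind `"FLASH"` or `"bSSFP"`.
#' @param slice_offset_mm signed slice offset in mm.
#' @param ap_threshold_mm AP threshold, inclusive (default 17 mm).
#' @return one of `"FLASH"`, `"AP_FLASH"`, `"bSSFP"`, `"AP_bSSFP"`.
#' @export
categorize_slice <- function(sequence_kind, slice_offset_mm,
                             ap_threshold_mm = 17) {
  if (!sequence_kind %in% c("FLASH", "bSSFP"))
    stop("unknown sequence_kind: ", sequence_kind)
  ap <- abs(slice_offset_mm) >= ap_threshold_mm
  if (ap) paste0("AP_", sequence_kind) else sequence_kind
}

slice_categories <- c("FLASH", "AP_FLASH", "bSSFP", "AP_bSSFP")

#' Compute integer balancing factors for category counts
#'
#' Each category is replicated by `factor = round(target / count)`
#' (half away from zero, minimum 1), so every category contributes a
#' near-equal number of images after augmentation. With the reference
#' category counts (1371, 21, 256, 18) and target 4330 this yields
#' factors (3, 206, 17, 241), per-category outputs (4113, 4326, 4352,
#' 4338) and a total of 17129.
#'
#' @param counts named integer vector of per-category image counts.
#' @param target common per-category target count (>= max count).
#' @return an `AugmentationPlan`: `data.frame` with columns `category`,
#'   `count`, `factor`, `resulting`, plus attribute `"total"`.
#' @export
compute_balancing_factors <- function(counts, target) {
  if (length(counts) == 0L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  zero <- counts == 0
  if (any(zero)) {
    warning("excluding zero-count categories: ",
            paste((names(counts) %||% seq_along(counts))[zero], collapse = ", "))
    counts <- counts[!zero]
  }
  if (length(counts) == 0L) stop("no non-empty categories")
  if (target < max(counts)) stop("target must be >= max(counts)")
  factor <- pmax(1, round_half_up(target / counts))
  plan <- data.frame(category = names(counts) %||% as.character(seq_along(counts)),
                     count = as.integer(counts),
                     factor = as.integer(factor),
                     resulting = as.integer(counts * factor),
                     stringsAsFactors = FALSE)
  attr(plan, "total") <- sum(plan$resulting)
  class(plan) <- c("AugmentationPlan", "data.frame")
  plan
}

#' @export
print.AugmentationPlan <- function(x, ...) {
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f%%", 100 * df$resulting / attr(x, "total"))
  print(df, row.names = FALSE)
  cat(sprintf("Total: %d images before, %d after augmentation\n",
              sum(df$count), attr(x, "total")))
  invisible(x)
}

#' Geometric transform parameters for augmentation
#'
#' Ranges for the jointly sampled transform tuple: shrink-only rescale,
#' per-axis translation magnitude in pixels (sign sampled uniformly),
#' and in-plane rotation. All three transforms are composed
#' (scale, then rotate, then translate) about the image centre with
#' zero padding; the grid size is unchanged.
#'
#' @param rescale_range zoom factor interval.
#' @param translate_px_range per-axis translation magnitude interval, px.
#' @param rotate_deg_range rotation interval in degrees.
#' @return a `TransformParams` object.
#' @export
transform_params <- function(rescale_range = c(0.3, 0.75),
                             translate_px_range = c(10, 20),
                             rotate_deg_range = c(0, 360)) {
  p <- list(rescale_range = as.numeric(rescale_range),
            translate_px_range = as.numeric(translate_px_range),
            rotate_deg_range = as.numeric(rotate_deg_range))
  for (nm in names(p))
    if (length(p[[nm]]) != 2L || p[[nm]][1] > p[[nm]][2])
      stop(nm, " must be an interval lo <= hi")
  structure(p, class = "TransformParams")
}

# forward transform: p_out = R(theta) * s * (p_in - c) + c + t
# inverse mapping used for resampling: p_in = R(-theta)/s * (p_out - c - t) + c
affine_inverse_coefs <- function(h, w, scale, tx, ty, theta_deg) {
  th <- theta_deg * pi / 180
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  Ainv <- t(R) / scale  # rotation inverse = transpose
  t_in <- c(cr, cc) - Ainv %*% c(cr + tx, cc + ty)
  c(Ainv[1, 1], Ainv[1, 2], Ainv[2, 1], Ainv[2, 2], t_in[1], t_in[2])
}

#' Apply one sampled geometric transform jointly to image and label
#'
#' Samples a single tuple (scale, translation, rotation) from the
#' configured ranges and applies the same transform to the image
#' (bilinear interpolation) and to the label (nearest neighbour, so the
#' label stays binary). Output grids keep the input shape; out-of-frame
#' pixels are zero.
#'
#' @param image an [Image2D].
#' @param label a [ContourLabel] (or [LungMask]) sharing the image grid.
#' @param params a [transform_params()].
#' @param seed RNG seed for the transform tuple.
#' @return list with transformed `image` and `label`, plus the sampled
#'   `transform` (scale, tx, ty, theta_deg).
#' @export
augment_pair <- function(image, label, params = transform_params(), seed = 1L) {
  img <- as_pixels(image)
  lab <- as_pixels(label)
  if (!all(dim(img) == dim(lab))) stop("image and label shapes differ")
  tr <- with_seed(seed, {
    sc <- runif(1, params$rescale_range[1], params$rescale_range[2])
    tmag <- runif(2, params$translate_px_range[1], params$translate_px_range[2])
    tsgn <- sample(c(-1, 1), 2L, replace = TRUE)
    th <- runif(1, params$rotate_deg_range[1], params$rotate_deg_range[2])
    list(scale = sc, tx = tmag[1] * tsgn[1], ty = tmag[2] * tsgn[2],
         theta_deg = th)
  })
  coefs <- affine_inverse_coefs(nrow(img), ncol(img),
                                tr$scale, tr$tx, tr$ty, tr$theta_deg)
  img_t <- warp_affine_cpp(img, coefs, nearest = 0L)
  lab_t <- warp_affine_cpp(lab * 1.0, coefs, nearest = 1L)
  spacing <- if (inherits(image, "Image2D")) image$spacing_mm else 500 / dim(img)
  out_label <- if (inherits(label, "LungMask")) {
    LungMask(lab_t, spacing)
  } else {
    ContourLabel(lab_t, if (inherits(label, "ContourLabel")) label$width_px else 6L)
  }
  list(image = Image2D(clip01(img_t), spacing), label = out_label,
       transform = tr)
}

#' Build an augmented training set
#'
#' Balanced mode emits, for every record of category `c`, `factor_c`
#' copies — the first copy being the untransformed original — so output
#' counts equal the plan's `resulting` column exactly. Conventional mode
#' emits `conv_copies` transformed copies plus the original for every
#' record regardless of category (the unbalanced baseline).
#'
#' @param records cohort records; each needs `image`, `label`,
#'   `sequence_kind`, `slice_offset_mm` (and optionally `mask`).
#' @param mode `"balanced"` or `"conventional"`.
#' @param plan an `AugmentationPlan` (balanced mode).
#' @param conv_copies augmented copies per image in conventional mode.
#' @param params a [transform_params()].
#' @param seed stream seed for the sampled transforms.
#' @param ap_threshold_mm AP category threshold in mm.
#' @return list of augmented records (`id`, `image`, `label`, `category`,
#'   `source_id`, `augmented`).
#' @export
build_training_set <- function(records, mode = c("balanced", "conventional"),
                               plan = NULL, conv_copies = 10L,
                               params = transform_params(), seed = 1L,
                               ap_threshold_mm = 17) {
  mode <- match.arg(mode)
  out <- vector("list", 0L)
  k <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    category <- categorize_slice(rec$sequence_kind, rec$slice_offset_mm,
                                 ap_threshold_mm)
    n_copies <- if (mode == "balanced") {
      if (is.null(plan)) stop("balanced mode requires a plan")
      row <- match(category, plan$category)
      if (is.na(row)) stop("category missing from plan: ", category)
      plan$factor[row]
    } else {
      conv_copies + 1L
    }
    for (j in seq_len(n_copies)) {
      k <- k + 1L
      if (j == 1L) {
        out[[k]] <- list(id = sprintf("%s_orig", rec$id %||% i),
                         image = rec$image, label = rec$label,
                         mask = rec$mask,
                         category = category,
                         source_id = rec$id %||% as.character(i),
                         augmented = FALSE)
      } else {
        aug <- augment_pair(rec$image, rec$label, params,
                            seed = derive_seed(seed, "augment",
                                               i * 10000L + j))
        # the mask rides along under the same transform (nearest neighbour)
        # so later stages (e.g. consolidation insertion) keep working on
        # augmented copies
        mask_t <- NULL
        if (!is.null(rec$mask)) {
          tr <- aug$transform
          coefs <- affine_inverse_coefs(nrow(as_pixels(rec$mask)),
                                        ncol(as_pixels(rec$mask)),
                                        tr$scale, tr$tx, tr$ty, tr$theta_deg)
          mp <- warp_affine_cpp(as_pixels(rec$mask) * 1.0, coefs,
                                nearest = 1L)
          # transforms may clip the lung at the frame edge; trim so the
          # mask object stays well-formed
          mp[c(1L, nrow(mp)), ] <- 0
          mp[, c(1L, ncol(mp))] <- 0
          mask_t <- LungMask(mp, rec$mask$spacing_mm)
        }
        out[[k]] <- list(id = sprintf("%s_aug%02d", rec$id %||% i, j - 1L),
                         image = aug$image, label = aug$label,
                         mask = mask_t,
                         category = category,
                         source_id = rec$id %||% as.character(i),
                         augmented = TRUE)
      }
    }
  }
  out
}

#' Size of a training set before building it
#'
#' Balanced mode: the plan's total (each image of category `c` emitted
#' `factor_c` times). Conventional mode: `n_images * (conv_copies + 1)`
#' (each image augmented `conv_copies` times plus the original).
#' [build_training_set()] emits exactly this many records.
#'
#' @param mode `"balanced"` or `"conventional"`.
#' @param plan an `AugmentationPlan` (balanced mode).
#' @param n_images number of input images (conventional mode).
#' @param conv_copies augmented copies per image (conventional mode).
#' @return integer record count.
#' @export
training_set_size <- function(mode = c("balanced", "conventional"),
                              plan = NULL, n_images = NULL,
                              conv_copies = 10L) {
  mode <- match.arg(mode)
  if (mode == "balanced") {
    if (is.null(plan)) stop("balanced mode requires a plan")
    sum(plan$resulting)
  } else {
    if (is.null(n_images)) stop("conventional mode requires n_images")
    as.integer(n_images) * (as.integer(conv_copies) + 1L)
  }
}

#' Tabulate category counts of a cohort
#'
#' @param records cohort records with `sequence_kind` and
#'   `slice_offset_mm`.
#' @param ap_threshold_mm AP category threshold in mm.
#' @return named integer vector over the categories present.
#' @export
category_counts <- function(records, ap_threshold_mm = 17) {
  cats <- vapply(records, function(r)
    categorize_slice(r$sequence_kind, r$slice_offset_mm, ap_threshold_mm), "")
  tab <- table(factor(cats, levels = slice_categories))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[counts > 0]
}
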