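#' Write a grayscale image or mask to disk
#'
#' PNG files are written 8-bit with intensities scaled by 255; `.nii` /
#' `.nii.gz` files are written as float32 with the pixel spacing in the
#' header (requires the RNifti package).
#'
#' @param x an [Image2D], [LungMask], [ContourLabel] or matrix.
#' @param path destination ending in `.png`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  p <- as_pixels(x)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(clip01(p), path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI output requires the RNifti package")
    spacing <- if (is.list(x) && !is.null(x$spacing_mm)) x$spacing_mm else c(1, 1)
    img <- RNifti::asNifti(array(p, c(dim(p), 1L)),
                           pixdim = c(spacing, 1))
    RNifti::writeNifti(img, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Read a grayscale image written by [write_image()]
#'
#' @param path source path.
#' @return numeric matrix in `[0, 1]` (PNG) or as stored (NIfTI).
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) > 2L) a <- a[, , 1L]
    a
  } else stop("unsupported image format: ", path)
}

#' Write cohort records and their manifest to a directory
#'
#' Saves each record's image, mask and (if present) label as PNG and a
#' `manifest.csv` with columns id, image_path, mask_path, label_path,
#' sequence_kind, slice_offset_mm.
#'
#' @param records cohort records.
#' @param dir destination directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    ip <- file.path(dir, paste0(r$id, "_image.png"))
    mp <- file.path(dir, paste0(r$id, "_mask.png"))
    write_image(r$image, ip)
    write_image(r$mask, mp)
    lp <- NA_character_
    if (!is.null(r$label)) {
      lp <- file.path(dir, paste0(r$id, "_label.png"))
      write_image(r$label, lp)
    }
    data.frame(id = r$id, image_path = ip, mask_path = mp, label_path = lp,
               sequence_kind = r$sequence_kind %||% NA_character_,
               slice_offset_mm = r$slice_offset_mm %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`.
#' @param matrix_size grid size used to restore pixel spacing.
#' @return list of records (id, image, mask, label if present,
#'   sequence_kind, slice_offset_mm).
#' @export
read_cohort <- function(dir, matrix_size = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- read_image(row$image_path)
    spacing <- 500 / dim(img)
    rec <- list(id = row$id,
                image = Image2D(img, spacing),
                mask = LungMask(read_image(row$mask_path) > 0.5, spacing),
                sequence_kind = row$sequence_kind,
                slice_offset_mm = row$slice_offset_mm)
    if (!is.na(row$label_path) && nzchar(row$label_path))
      rec$label <- ContourLabel(read_image(row$label_path) > 0.5)
    rec
  })
}
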