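#' Localised knee-joint region of interest
#'
#' Container for one localised knee-joint image as produced by an external
#' joint-localisation step: raw (16-bit range) intensities, the physical
#' pixel spacing, the anatomical side and, when available, the
#' Kellgren-Lawrence grade annotation.
#'
#' @param pixels numeric matrix of intensities (rows = image rows); both
#'   dimensions must be at least 8.
#' @param spacing_mm physical size of one pixel in millimetres (scalar > 0),
#'   as carried e.g. by the DICOM `ImagerPixelSpacing` tag.
#' @param side `"left"` or `"right"`.
#' @param kl_grade optional integer KL grade in 0..4 (`NA` if ungraded).
#' @param source_id opaque identifier string.
#'
#' @return An object of class `knee_roi`.
#' @export
knee_roi <- function(pixels, spacing_mm, side = c("right", "left"),
                     kl_grade = NA_integer_, source_id = "") {
  side <- match.arg(side)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop("`pixels` must be at least 8x8")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("`spacing_mm` must be a positive scalar")
  if (!is.na(kl_grade)) {
    if (kl_grade != as.integer(kl_grade) || kl_grade < 0 || kl_grade > 4)
      stop("`kl_grade` must be an integer in 0..4")
    kl_grade <- as.integer(kl_grade)
  } else {
    kl_grade <- NA_integer_
  }
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm), side = side,
         kl_grade = kl_grade, source_id = as.character(source_id)),
    class = "knee_roi"
  )
}

#' @export
print.knee_roi <- function(x, ...) {
  cat(sprintf("<knee_roi '%s'> %dx%d px @ %.4g mm/px, %s knee, KL %s\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              x$side, ifelse(is.na(x$kl_grade), "?", x$kl_grade)))
  invisible(x)
}

#' Normalised 8-bit knee image
#'
#' An intensity-normalised image with values in \[0, 255\] plus the physical
#' geometry needed for millimetre-level cropping.
#'
#' @param pixels numeric matrix with all values in \[0, 255\].
#' @param spacing_mm pixel spacing in mm.
#' @param kl_grade,source_id carried over from the source ROI.
#' @return An object of class `knee_norm` with fields `pixels`, `spacing_mm`,
#'   `physical_size_mm` (height, width), `kl_grade`, `source_id`.
#' @export
knee_norm <- function(pixels, spacing_mm, kl_grade = NA_integer_,
                      source_id = "") {
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("normalised intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
         physical_size_mm = c(nrow(pixels), ncol(pixels)) * spacing_mm,
         kl_grade = kl_grade, source_id = as.character(source_id)),
    class = "knee_norm"
  )
}

#' @export
print.knee_norm <- function(x, ...) {
  cat(sprintf("<knee_norm '%s'> %dx%d px (%.1f x %.1f mm), range [%.1f, %.1f]\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$physical_size_mm[1], x$physical_size_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read and write 16-bit knee ROI images with JSON sidecar metadata
#'
#' The on-disk interchange format for raw ROIs is a 16-bit grayscale TIFF
#' next to a JSON sidecar (`<image>.json`) holding `spacing_mm`, `side`,
#' `kl_grade` and `source_id`.
#'
#' @param roi a [knee_roi()].
#' @param path image file path (`.tif`/`.tiff`).
#' @return `read_knee_image()` returns a [knee_roi()]; `write_knee_image()`
#'   returns `path` invisibly.
#' @export
write_knee_image <- function(roi, path) {
  stopifnot(inherits(roi, "knee_roi"))
  tiff::writeTIFF(pmin(pmax(roi$pixels, 0), 65535) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  meta <- list(spacing_mm = roi$spacing_mm, side = roi$side,
               kl_grade = roi$kl_grade, source_id = roi$source_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_knee_image
#' @export
read_knee_image <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  kl <- meta$kl_grade
  knee_roi(round(px * 65535), spacing_mm = meta$spacing_mm, side = meta$side,
           kl_grade = if (is.null(kl)) NA_integer_ else kl,
           source_id = if (is.null(meta$source_id)) "" else meta$source_id)
}

#' Read a knee-joint bounding-box table
#'
#' Plain CSV with one row per knee: `image` (path), `side` (`left`/`right`),
#' `x`, `y`, `width`, `height` in pixels, 0-based, half-open, and optionally
#' `kl_grade`.
#'
#' @param path CSV file path.
#' @return A `data.frame` with the columns above.
#' @export
read_bbox_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "side", "x", "y", "width", "height")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("bounding-box file is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Cut a bounding box out of a full image
#'
#' @param pixels full-image intensity matrix.
#' @param bbox one row of a [read_bbox_csv()] table (list/data.frame with
#'   `x`, `y`, `width`, `height`, 0-based half-open).
#' @param spacing_mm,side,kl_grade,source_id metadata for the resulting ROI.
#' @return A [knee_roi()].
#' @export
crop_bbox <- function(pixels, bbox, spacing_mm, side, kl_grade = NA_integer_,
                      source_id = "") {
  x0 <- bbox$x; y0 <- bbox$y
  if (x0 < 0 || y0 < 0 || x0 + bbox$width > ncol(pixels) ||
      y0 + bbox$height > nrow(pixels))
    stop("bounding box exceeds image bounds")
  knee_roi(pixels[(y0 + 1):(y0 + bbox$height), (x0 + 1):(x0 + bbox$width)],
           spacing_mm, side, kl_grade, source_id)
}
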