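#' Percentile truncation and 8-bit rescaling
#'
#' Converts a raw (16-bit range) ROI to 8-bit: intensities are clipped to
#' the given low/high percentiles of the image's own histogram and then
#' affinely mapped so the clip bounds become 0 and 255. This is the global
#' contrast normalisation applied before any geometric processing; it
#' suppresses detector noise and outlier pixels.
#'
#' Values are quantised with round-half-to-even and clipped to \[0, 255\].
#'
#' @param roi a [knee_roi()].
#' @param lo_pct,hi_pct truncation percentiles, defaults 5 and 99.
#' @return A [knee_norm()] image.
#' @export
truncate_and_rescale <- function(roi, lo_pct = 5, hi_pct = 99) {
  stopifnot(inherits(roi, "knee_roi"))
  if (lo_pct >= hi_pct) stop("`lo_pct` must be smaller than `hi_pct`")
  q <- stats::quantile(roi$pixels, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[1] >= q[2])
    stop("degenerate image: the ", lo_pct, "th and ", hi_pct,
         "th percentiles coincide")
  v <- pmin(pmax(roi$pixels, q[1]), q[2])
  v <- round((v - q[1]) / (q[2] - q[1]) * 255)
  v <- pmin(pmax(v, 0), 255)
  knee_norm(v, roi$spacing_mm, roi$kl_grade, roi$source_id)
}

#' Mirror left knees into right-knee orientation
#'
#' Left knees are flipped about the vertical axis and relabelled `"right"`
#' so that a single model can be trained on anatomically consistent images;
#' right knees pass through unchanged. Applying the operation twice to a
#' left knee returns the original pixels (with the side label now fixed).
#'
#' @param roi a [knee_roi()].
#' @return A [knee_roi()] in right-knee orientation.
#' @export
flip_if_left <- function(roi) {
  stopifnot(inherits(roi, "knee_roi"))
  if (roi$side == "right") return(roi)
  roi$pixels <- roi$pixels[, rev(seq_len(ncol(roi$pixels))), drop = FALSE]
  roi$side <- "right"
  roi
}

#' Centre crop to a fixed physical size
#'
#' Crops the centred square region of the requested physical side length,
#' using the image's pixel spacing; e.g. a 140 mm ROI at 0.5 mm/px cropped
#' to 130 mm yields a 260x260 px image. When the margin is odd the extra
#' pixel is dropped from the top/left, i.e. it remains on the bottom/right.
#'
#' @param img a [knee_norm()] image.
#' @param target_mm physical side length of the crop in millimetres.
#' @return A [knee_norm()] image of the cropped region.
#' @export
center_crop_mm <- function(img, target_mm) {
  stopifnot(inherits(img, "knee_norm"))
  t_px <- round(target_mm / img$spacing_mm)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  if (t_px > h || t_px > w)
    stop(sprintf("crop of %.1f mm (%d px) exceeds image size %dx%d px",
                 target_mm, t_px, h, w))
  top <- (h - t_px) %/% 2
  left <- (w - t_px) %/% 2
  knee_norm(img$pixels[(top + 1):(top + t_px), (left + 1):(left + t_px)],
            img$spacing_mm, img$kl_grade, img$source_id)
}

#' Gamma correction
#'
#' Maps each intensity v to `255 * (v/255)^gamma`. The map is strictly
#' monotone for any positive gamma and fixes 0 and 255, so it changes
#' mid-tone contrast without moving the endpoints; gamma < 1 brightens,
#' gamma > 1 darkens.
#'
#' @param img a [knee_norm()] image.
#' @param gamma positive exponent.
#' @return A [knee_norm()] image (intensities kept continuous).
#' @export
gamma_correct <- function(img, gamma) {
  stopifnot(inherits(img, "knee_norm"))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("`gamma` must be a positive scalar")
  knee_norm(255 * (img$pixels / 255)^gamma, img$spacing_mm, img$kl_grade,
            img$source_id)
}

#' Exposure-triggered gamma correction
#'
#' Test-time fix for over-/under-exposed images: if the mean intensity lies
#' outside the configured band the first gamma from `gammas` that brings the
#' mean into the band is applied (falling back to the gamma whose resulting
#' mean is closest to the band if none succeeds); images already inside the
#' band pass through untouched.
#'
#' @param img a [knee_norm()] image.
#' @param band acceptable mean-intensity range, default `c(60, 180)`.
#' @param gammas candidate gammas tried in order.
#' @return A [knee_norm()] image.
#' @export
auto_exposure_gamma <- function(img, band = c(60, 180),
                                gammas = c(0.5, 0.67, 1.5, 2.0)) {
  stopifnot(inherits(img, "knee_norm"), length(band) == 2, band[1] < band[2])
  m <- mean(img$pixels)
  if (m >= band[1] && m <= band[2]) return(img)
  means <- vapply(gammas, function(g) mean(255 * (img$pixels / 255)^g),
                  numeric(1))
  ok <- which(means >= band[1] & means <= band[2])
  pick <- if (length(ok)) ok[1] else {
    dist <- pmax(band[1] - means, means - band[2], 0)
    which.min(dist)
  }
  gamma_correct(img, gammas[pick])
}
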