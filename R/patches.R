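#' Geometry of the symmetric lateral/medial patch pair
#'
#' Describes how the two square S x S patches are cut from the resized
#' joint image: the lateral patch is anchored at the left edge (x = 0) and
#' the medial patch, with the default `"opposite"` variant, at the right
#' edge (x = resized_px - S), both with their top edge at y = K. The
#' `"literal"` variant instead places the medial patch at x = S - K; it is
#' kept constructible because the two readings of the patch layout differ,
#' but the opposite-edge variant is the default since it is the one that
#' actually covers the medial compartment.
#'
#' Coordinates are 0-based pixel offsets in the resized image frame.
#'
#' @param resized_px side length of the resized joint image (default 300).
#' @param S patch side length in pixels (default 128).
#' @param K shared vertical offset of both patches in pixels (default 100).
#' @param variant `"opposite"` (default) or `"literal"` medial placement.
#' @param medial_x optional explicit medial x-origin, overriding `variant`.
#' @return An object of class `patch_geometry` with fields `resized_px`,
#'   `S`, `K`, `lateral_origin`, `medial_origin` (each `c(x, y)`).
#' @export
patch_geometry <- function(resized_px = 300L, S = 128L, K = 100L,
                           variant = c("opposite", "literal"),
                           medial_x = NULL) {
  variant <- match.arg(variant)
  resized_px <- as.integer(resized_px); S <- as.integer(S); K <- as.integer(K)
  if (S > resized_px) stop("patch side S must not exceed resized_px")
  if (is.null(medial_x))
    medial_x <- if (variant == "opposite") resized_px - S else S - K
  medial_x <- as.integer(medial_x)
  geom <- structure(
    list(resized_px = resized_px, S = S, K = K,
         lateral_origin = c(x = 0L, y = K),
         medial_origin = c(x = medial_x, y = K)),
    class = "patch_geometry"
  )
  for (o in list(geom$lateral_origin, geom$medial_origin)) {
    if (o["x"] < 0 || o["y"] < 0 || o["x"] + S > resized_px ||
        o["y"] + S > resized_px)
      stop("patch geometry places an SxS patch outside the resized image")
  }
  geom
}

#' @export
print.patch_geometry <- function(x, ...) {
  cat(sprintf(
    "<patch_geometry> %dpx grid, S=%d, K=%d; lateral @(%d,%d), medial @(%d,%d)\n",
    x$resized_px, x$S, x$K, x$lateral_origin["x"], x$lateral_origin["y"],
    x$medial_origin["x"], x$medial_origin["y"]))
  invisible(x)
}

#' Resize a normalised image to the fixed pixel grid
#'
#' Bilinear (endpoint-aligned) resampling of the fixed-physical-size crop to
#' the square pixel grid the patch geometry is defined on, e.g. the 130 mm
#' crop to 300 x 300 px.
#'
#' @param img a [knee_norm()] image or plain intensity matrix.
#' @param resized_px output side length.
#' @return An intensity matrix of size `resized_px` x `resized_px`.
#' @export
resize_to_grid <- function(img, resized_px = 300L) {
  px <- if (inherits(img, "knee_norm")) img$pixels else img
  resize_bilinear(px, resized_px, resized_px)
}

#' Extract the lateral/medial patch pair
#'
#' Cuts the lateral patch at `lateral_origin` and the medial patch at
#' `medial_origin`, horizontally flipping the medial one so that both
#' patches are in the same (lateral-like) orientation — the premise that
#' lets one shared-weight branch serve both sides of the joint.
#'
#' @param img resized intensity matrix (`resized_px` x `resized_px`).
#' @param geom a [patch_geometry()].
#' @param source_id identifier carried along.
#' @return An object of class `patch_pair` with fields `lateral`, `medial`
#'   (both S x S, medial stored flipped), `geometry`, `source_id`.
#' @export
extract_pair <- function(img, geom = patch_geometry(), source_id = "") {
  px <- if (inherits(img, "knee_norm")) img$pixels else img
  if (nrow(px) != geom$resized_px || ncol(px) != geom$resized_px)
    stop(sprintf("image is %dx%d but geometry expects %dx%d",
                 nrow(px), ncol(px), geom$resized_px, geom$resized_px))
  S <- geom$S
  cut <- function(origin) {
    px[(origin["y"] + 1):(origin["y"] + S),
       (origin["x"] + 1):(origin["x"] + S), drop = FALSE]
  }
  lateral <- cut(geom$lateral_origin)
  medial <- cut(geom$medial_origin)[, S:1, drop = FALSE]
  structure(list(lateral = lateral, medial = medial, geometry = geom,
                 source_id = as.character(source_id)),
            class = "patch_pair")
}

#' @export
print.patch_pair <- function(x, ...) {
  cat(sprintf("<patch_pair '%s'> two %dx%d patches (medial stored flipped)\n",
              x$source_id, x$geometry$S, x$geometry$S))
  invisible(x)
}

#' Map patch coordinates back to the resized-image frame
#'
#' Exact inverse of the coordinate mapping used by [extract_pair()],
#' including the horizontal un-flip for the medial side; needed to project
#' attention maps back onto the joint image. Coordinates are 0-based; `xy`
#' may be a length-2 vector or a 2-column matrix of `(x, y)` pairs.
#'
#' @param xy coordinates in the (stored) patch frame.
#' @param which `"lateral"` or `"medial"`.
#' @param geom a [patch_geometry()].
#' @return Coordinates in the resized-image frame, same shape as `xy`.
#' @export
project_patch_to_image <- function(xy, which = c("lateral", "medial"),
                                   geom = patch_geometry()) {
  which <- match.arg(which)
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  if (any(m < 0) || any(m > geom$S - 1))
    stop("coordinates fall outside the SxS patch")
  out <- m
  if (which == "lateral") {
    out[, 1] <- geom$lateral_origin["x"] + m[, 1]
    out[, 2] <- geom$lateral_origin["y"] + m[, 2]
  } else {
    out[, 1] <- geom$medial_origin["x"] + (geom$S - 1 - m[, 1])
    out[, 2] <- geom$medial_origin["y"] + m[, 2]
  }
  if (is.matrix(xy)) out else drop(out)
}
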