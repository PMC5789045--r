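#' Class-discriminating attention maps for one Siamese model
#'
#' Grad-CAM adapted to the shared-weight two-branch architecture. For each
#' branch i the class score y_c is differentiated with respect to that
#' branch's pooled features; because the maps feed a global average pooling
#' followed by a linear head, this gradient equals the spatially averaged
#' per-pixel gradient of y_c at the pre-GAP activation maps (up to the
#' constant 1/(XY), which cancels under the final min-max normalisation).
#' The branch map is the ReLU of the gradient-weighted sum of its
#' activation maps, so only features whose increase would raise the class
#' score survive.
#'
#' For the same reason the choice between plain and "guided"
#' backpropagation is immaterial here: no ReLU lies between the pre-GAP
#' maps and the class score, so both gradient rules coincide at the layer
#' the weights are read from.
#'
#' @param net a [siamese_net()].
#' @param pair a `patch_pair`.
#' @param class target KL grade in 0..4 (`"argmax"` to use the predicted
#'   grade).
#' @return An object of class `attention_pair`: non-negative `lateral_map`
#'   and `medial_map` (in the flipped patch frame), the `target_class`, the
#'   pair's `geometry` and the class score `y_c`.
#' @export
branch_cam <- function(net, pair, class = "argmax") {
  stopifnot(inherits(pair, "patch_pair"))
  fw <- siamese_forward(net, list(pair), training = FALSE)
  logits <- drop(fw$logits)
  if (identical(class, "argmax")) class <- which.max(logits) - 1L
  if (!is.numeric(class) || class < 0 || class >= net$n_classes)
    stop("`class` must be a KL grade in 0..", net$n_classes - 1L)
  cls <- as.integer(class)
  C <- net$spec$widths[5]
  maps <- fw$branch$maps                       # (X, Y, 2, C): lateral, medial
  d <- dim(maps)
  cam_one <- function(i) {
    w <- net$params$head_W[cls + 1L, (i - 1L) * C + seq_len(C)]
    m_i <- matrix(maps[, , i, , drop = FALSE], d[1] * d[2], C)
    m <- matrix(m_i %*% w, d[1], d[2])
    m[m < 0] <- 0
    m
  }
  structure(list(lateral_map = cam_one(1L), medial_map = cam_one(2L),
                 target_class = cls, geometry = pair$geometry,
                 y_c = logits[cls + 1L]),
            class = "attention_pair")
}

#' Ensemble attention maps
#'
#' The ensemble analogue: each member's branch maps are computed for the
#' same target class and summed entrywise per branch. Because the fused
#' class score is the sum of the member scores and gradients are linear,
#' this entrywise sum is the Grad-CAM of the fused score.
#'
#' @param bundle an [ensemble_bundle()].
#' @param pair a `patch_pair`.
#' @param class target KL grade in 0..4, or `"argmax"` of the fused
#'   distribution.
#' @return An `attention_pair` (see [branch_cam()]).
#' @export
ensemble_cam <- function(bundle, pair, class = "argmax") {
  stopifnot(inherits(bundle, "ensemble_bundle"))
  if (identical(class, "argmax"))
    class <- which.max(fuse(bundle, pair)) - 1L
  cams <- lapply(bundle$members, branch_cam, pair = pair, class = class)
  dims <- lapply(cams, function(a) dim(a$lateral_map))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("ensemble members produced attention maps of different sizes")
  out <- cams[[1]]
  if (length(cams) > 1) {
    for (a in cams[-1]) {
      out$lateral_map <- out$lateral_map + a$lateral_map
      out$medial_map <- out$medial_map + a$medial_map
    }
    out$y_c <- sum(vapply(cams, function(a) a$y_c, numeric(1)))
  }
  out
}

#' Project attention maps onto the joint image
#'
#' Renders the per-branch maps as one heatmap in the resized-image frame:
#' each low-resolution map is upsampled to S x S (endpoint-aligned
#' bilinear), the medial map is horizontally un-flipped, both are pasted at
#' their patch origins onto a zero canvas (max-blended where patches
#' overlap) and the canvas is min-max normalised to \[0, 1\]. An
#' identically zero raw map yields an all-zero overlay.
#'
#' @param maps an `attention_pair` from [branch_cam()]/[ensemble_cam()].
#' @param geom a [patch_geometry()] (defaults to the pair's own).
#' @param resized_px canvas side length (defaults to the geometry's).
#' @return An object of class `attention_overlay` with fields `heatmap`
#'   (matrix in \[0, 1\]) and `target_class`.
#' @export
render_overlay <- function(maps, geom = maps$geometry,
                           resized_px = geom$resized_px) {
  stopifnot(inherits(maps, "attention_pair"))
  S <- geom$S
  lat <- resize_bilinear(maps$lateral_map, S, S)
  med <- resize_bilinear(maps$medial_map, S, S)[, S:1, drop = FALSE]
  canvas <- matrix(0, resized_px, resized_px)
  paste_max <- function(canvas, patch, origin) {
    rr <- (origin["y"] + 1):(origin["y"] + S)
    cc <- (origin["x"] + 1):(origin["x"] + S)
    canvas[rr, cc] <- pmax(canvas[rr, cc], patch)
    canvas
  }
  canvas <- paste_max(canvas, lat, geom$lateral_origin)
  canvas <- paste_max(canvas, med, geom$medial_origin)
  rng <- range(canvas)
  heat <- if (rng[2] > rng[1]) (canvas - rng[1]) / (rng[2] - rng[1])
          else matrix(0, resized_px, resized_px)
  structure(list(heatmap = heat, target_class = maps$target_class),
            class = "attention_overlay")
}

#' @export
print.attention_overlay <- function(x, ...) {
  cat(sprintf("<attention_overlay> %dx%d heatmap for KL-%d, mass %.3f\n",
              nrow(x$heatmap), ncol(x$heatmap), x$target_class,
              mean(x$heatmap)))
  invisible(x)
}

#' @export
plot.attention_overlay <- function(x, y = NULL, image = NULL, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  flip_rows <- function(m) m[nrow(m):1, , drop = FALSE]
  if (!is.null(image)) {
    px <- if (inherits(image, "knee_norm")) image$pixels else image
    graphics::image(t(flip_rows(px)), col = grDevices::gray.colors(256),
                    axes = FALSE, useRaster = TRUE,
                    main = sprintf("attention, KL-%d", x$target_class))
    cols <- grDevices::hcl.colors(64, "inferno", alpha = 0.45)
    graphics::image(t(flip_rows(x$heatmap)), col = cols, add = TRUE,
                    useRaster = TRUE)
  } else {
    graphics::image(t(flip_rows(x$heatmap)),
                    col = grDevices::hcl.colors(64, "inferno"),
                    axes = FALSE, useRaster = TRUE,
                    main = sprintf("attention, KL-%d", x$target_class))
  }
  invisible(x)
}
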