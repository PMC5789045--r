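# Shared bilinear resampling core. All geometric operations in the package
# (grid resizing, rotation/jitter augmentation, attention-map upsampling) go
# through this sampler so interpolation conventions are stated once:
# coordinates are 0-based with x = column and y = row, the grid is
# endpoint-aligned (corner pixels map to corner pixels), and samples outside
# the image are clamped to the nearest edge pixel.

bilinear_sample <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x)
  y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0
  fy <- y - y0
  # column-major linear indices
  i00 <- y0 + 1 + x0 * h
  i01 <- y0 + 1 + x1 * h
  i10 <- y1 + 1 + x0 * h
  i11 <- y1 + 1 + x1 * h
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# Endpoint-aligned bilinear resize: the four corner intensities are preserved
# exactly for any output size > 1.
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img)
  w <- ncol(img)
  ys <- if (out_h == 1L) (h - 1) / 2 else seq(0, h - 1, length.out = out_h)
  xs <- if (out_w == 1L) (w - 1) / 2 else seq(0, w - 1, length.out = out_w)
  gx <- rep(xs, each = out_h)
  gy <- rep(ys, times = out_w)
  matrix(bilinear_sample(img, gx, gy), out_h, out_w)
}

# Sample `img` on an out_h x out_w grid through an affine map: the 3x3 matrix
# `A` sends homogeneous output coordinates (x, y, 1) (0-based) to source
# coordinates. Used by the augmentation pipeline, where rotation, jitter and
# cropping compose into a single resampling pass.
warp_affine <- function(img, A, out_h, out_w) {
  gx <- rep(seq_len(out_w) - 1, each = out_h)
  gy <- rep(seq_len(out_h) - 1, times = out_w)
  sx <- A[1, 1] * gx + A[1, 2] * gy + A[1, 3]
  sy <- A[2, 1] * gx + A[2, 2] * gy + A[2, 3]
  matrix(bilinear_sample(img, sx, sy), out_h, out_w)
}

affine_identity <- function() diag(3)

affine_translate <- function(dx, dy) {
  A <- diag(3)
  A[1, 3] <- dx
  A[2, 3] <- dy
  A
}

# Rotation by `deg` degrees (counter-clockwise in image coordinates) about
# the point (cx, cy), 0-based.
affine_rotate <- function(deg, cx, cy) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0,
                -sin(th), cos(th), 0,
                0, 0, 1), 3, 3)
  affine_translate(cx, cy) %*% R %*% affine_translate(-cx, -cy)
}
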