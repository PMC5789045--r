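make_test_roi <- function(values, side = "right", spacing = 0.5) {
  n <- ceiling(sqrt(length(values)))
  v <- rep_len(values, n * n)
  knee_roi(matrix(v, n, n), spacing_mm = spacing, side = side,
           source_id = "t")
}

test_that("percentile truncation maps the clip bounds to 0 and 255", {
  # sorted 16x16 image engineered so the 5th/99th percentiles are exactly
  # 1000 and 9000, with 5000 present in between
  v <- sort(c(rep(500, 12), rep(1000, 2), seq(1200, 8800, length.out = 235),
              5000, rep(9000, 4), 60000, 65000))
  stopifnot(length(v) == 256)
  roi <- make_test_roi(v)
  q <- quantile(roi$pixels, c(0.05, 0.99), names = FALSE)
  expect_equal(q, c(1000, 9000))

  img <- truncate_and_rescale(roi, 5, 99)
  expect_s3_class(img, "knee_norm")
  expect_equal(img$pixels[roi$pixels == 1000][1], 0)
  expect_equal(img$pixels[roi$pixels == 9000][1], 255)
  expect_equal(img$pixels[roi$pixels == 500][1], 0)     # clipped below
  expect_equal(img$pixels[roi$pixels == 65000][1], 255) # clipped above
  # (5000 - 1000)/8000 * 255 = 127.5, round-half-to-even -> 128
  expect_equal(img$pixels[roi$pixels == 5000][1], 128)
})

test_that("truncation is idempotent up to quantisation and rejects bad input", {
  set.seed(1)
  roi <- make_test_roi(runif(400, 0, 65535))
  a <- truncate_and_rescale(roi)
  b <- truncate_and_rescale(knee_roi(a$pixels, roi$spacing_mm, "right"))
  expect_lt(max(abs(a$pixels - b$pixels)), 4)
  expect_error(truncate_and_rescale(make_test_roi(rep(7, 256))),
               "degenerate")
  expect_error(truncate_and_rescale(roi, 99, 5), "lo_pct")
})

test_that("left knees are mirrored and relabelled, right knees untouched", {
  set.seed(2)
  px <- matrix(runif(256, 0, 65535), 16, 16)
  px[, 1] <- 60000   # bright column at x = 0
  left <- knee_roi(px, 0.5, "left")
  right <- knee_roi(px, 0.5, "right")

  expect_identical(flip_if_left(right)$pixels, px)
  flipped <- flip_if_left(left)
  expect_equal(flipped$side, "right")
  expect_equal(flipped$pixels[, 16], px[, 1])  # bright column now at x = W-1
  # involution: flipping the already-flipped image (relabelled left again)
  again <- flip_if_left(knee_roi(flipped$pixels, 0.5, "left"))
  expect_equal(again$pixels, px)
})

test_that("centre crop honours physical size and margin convention", {
  px <- matrix(rep(seq_len(280), 280), 280, 280)  # pixel value = row index
  img <- knee_norm(px / 280 * 255, spacing_mm = 0.5)

  cr <- center_crop_mm(img, 130)
  expect_equal(dim(cr$pixels), c(260, 260))
  expect_equal(cr$physical_size_mm, c(130, 130))
  # even margin 20 px: rows 11..270
  expect_equal(cr$pixels[1, 1], px[11, 1] / 280 * 255)

  # odd margin: 261 px crop leaves 19 px, split 9 top / 10 bottom
  odd <- center_crop_mm(img, 130.5)
  expect_equal(dim(odd$pixels), c(261, 261))
  expect_equal(odd$pixels[1, 1], px[10, 1] / 280 * 255)

  expect_equal(center_crop_mm(img, 140)$pixels, img$pixels)  # identity
  expect_error(center_crop_mm(img, 150), "exceeds")
})

test_that("gamma correction is monotone with fixed endpoints", {
  v <- matrix(seq(0, 255, length.out = 64), 8, 8)
  img <- knee_norm(v, 0.5)

  expect_equal(gamma_correct(img, 1)$pixels, v)
  for (g in c(0.4, 2.5)) {
    out <- gamma_correct(img, g)$pixels
    expect_equal(out[1], 0)
    expect_equal(out[64], 255)
    expect_true(all(diff(as.vector(out)) > 0))  # order preserved
  }
  expect_equal(gamma_correct(knee_norm(matrix(64, 8, 8), 0.5), 2)$pixels[1],
               255 * (64 / 255)^2, tolerance = 1e-12)
  expect_error(gamma_correct(img, 0), "positive")
  expect_error(gamma_correct(img, -1), "positive")
})

test_that("exposure-triggered gamma moves the mean toward the band", {
  mid <- knee_norm(matrix(runif(256, 80, 160), 16, 16), 0.5)
  expect_identical(auto_exposure_gamma(mid)$pixels, mid$pixels)

  dark <- knee_norm(matrix(20, 16, 16), 0.5)
  expect_gt(mean(auto_exposure_gamma(dark)$pixels), 20)

  bright <- knee_norm(matrix(240, 16, 16), 0.5)
  expect_lt(mean(auto_exposure_gamma(bright)$pixels), 240)
})
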