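test_that("phantoms are reproducible and carry their annotations", {
  a <- make_phantom(2, seed = 300)
  b <- make_phantom(2, seed = 300)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, make_phantom(2, seed = 301)$pixels))
  expect_equal(a$kl_grade, 2L)
  expect_equal(dim(a$pixels), c(280, 280))
  expect_true(all(a$pixels >= 0 & a$pixels <= 65535))
  expect_true(is.matrix(attr(a, "margin_mask")))
  expect_gt(sum(attr(a, "margin_mask")), 0)
  expect_error(make_phantom(5), "grade")
})

test_that("noise-free joint spaces order the grades exactly", {
  cfg <- quiet_phantom_config()
  gaps <- vapply(0:4, function(g)
    measure_joint_space(make_phantom(g, cfg, seed = 310 + g)), numeric(1))
  expect_true(all(diff(gaps) < 0))                  # strictly narrowing
  expect_equal(gaps, cfg$joint_space_mm, tolerance = 0.5)
  expect_lt(measure_joint_space(make_phantom(4, cfg, seed = 1)),
            measure_joint_space(make_phantom(0, cfg, seed = 1)))
})

test_that("default noise makes adjacent grades overlap but stay learnable", {
  set.seed(311)
  g0 <- vapply(1:40, function(i)
    attr(make_phantom(0, seed = 1000 + i), "gap_mm"), numeric(1))
  g1 <- vapply(1:40, function(i)
    attr(make_phantom(1, seed = 2000 + i), "gap_mm"), numeric(1))
  expect_gt(mean(g0), mean(g1))            # signal present
  expect_gt(max(g1), min(g0))              # distributions overlap
})

test_that("subchondral bands brighten with grade on noise-free phantoms", {
  cfg <- quiet_phantom_config()
  band_mean <- function(g) {
    r <- make_phantom(g, cfg, seed = 320)
    n <- nrow(r$pixels)
    gap_px <- cfg$joint_space_mm[g + 1] / cfg$spacing_mm
    rows <- round(n / 2 - gap_px / 2 - 3):round(n / 2 - gap_px / 2 - 1)
    mean(r$pixels[rows, (0.3 * n):(0.7 * n)])
  }
  expect_gt(band_mean(4), band_mean(0))
})

test_that("datasets are balanced, split-disjoint and manifest-stable", {
  ds <- make_dataset(10, seed = 330)
  expect_length(ds$rois, 50)
  expect_equal(unname(table(ds$manifest$grade)), rep(10L, 5),
               ignore_attr = TRUE)
  expect_equal(as.integer(table(ds$manifest$split)[c("train", "val",
                                                     "test")]),
               c(30L, 10L, 10L))
  # splits stratified: each grade contributes to each split
  tab <- table(ds$manifest$grade, ds$manifest$split)
  expect_true(all(tab > 0))
  # ids unique and disjoint across splits by construction
  expect_equal(anyDuplicated(ds$manifest$id), 0L)

  ds2 <- make_dataset(10, seed = 330)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$rois[[17]]$pixels, ds2$rois[[17]]$pixels)
})

test_that("every phantom passes the preprocessing and patch pipeline", {
  ds <- make_dataset(2, seed = 340)
  geom <- patch_geometry()
  for (r in ds$rois) {
    pp <- extract_pair(
      resize_to_grid(center_crop_mm(truncate_and_rescale(r), 130), 300),
      geom, source_id = r$source_id)
    expect_equal(dim(pp$lateral), c(128, 128))
    expect_true(all(is.finite(pp$medial)))
  }
})

test_that("joint margins fall inside both extracted patches", {
  geom <- patch_geometry()
  r <- make_phantom(3, seed = 350)
  mask <- attr(r, "margin_mask")
  t_px <- round(130 / r$spacing_mm)
  top <- (nrow(mask) - t_px) %/% 2
  mc <- mask[(top + 1):(top + t_px), (top + 1):(top + t_px)]
  mr <- resize_bilinear(mc * 1, 300, 300) > 0.5

  lat <- mr[(geom$lateral_origin["y"] + 1):(geom$lateral_origin["y"] + 128),
            (geom$lateral_origin["x"] + 1):(geom$lateral_origin["x"] + 128)]
  med <- mr[(geom$medial_origin["y"] + 1):(geom$medial_origin["y"] + 128),
            (geom$medial_origin["x"] + 1):(geom$medial_origin["x"] + 128)]
  expect_gt(sum(lat), 100)
  expect_gt(sum(med), 100)
})

test_that("run-length masks round-trip", {
  set.seed(360)
  m <- matrix(runif(400) > 0.6, 20, 20)
  expect_identical(rle_to_mask(mask_to_rle(m)), m)
  all_true <- matrix(TRUE, 4, 4)
  expect_identical(rle_to_mask(mask_to_rle(all_true)), all_true)
})

test_that("phantom configuration enforces feature monotonicity", {
  expect_error(phantom_config(joint_space_mm = c(6, 5, 5, 2.5, 1)),
               "decreasing")
  expect_error(phantom_config(osteophyte_amp = c(0.5, 0.1, 0.2, 0.3, 0.4)),
               "non-decreasing")
})
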