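test_that("zero head weights for a branch give an identically zero map", {
  net <- siamese_net(small_spec(), seed = 50)
  C <- net$spec$widths[5]
  net$params$head_W[3, seq_len(C)] <- 0   # class 2, branch 1 block
  cam <- branch_cam(net, random_pair(24, seed = 51), class = 2)
  expect_true(all(cam$lateral_map == 0))
  expect_true(all(cam$lateral_map >= 0) && all(cam$medial_map >= 0))
  expect_error(branch_cam(net, random_pair(24, seed = 51), class = 7),
               "grade")
})

test_that("maps equal the ReLU of head-weighted activation maps (closed form)", {
  net <- siamese_net(small_spec(), seed = 52)
  pp <- random_pair(24, seed = 53)
  cls <- 3L
  cam <- branch_cam(net, pp, class = cls)

  # hand path: standardise, run the branch, weight by the head block
  v <- c(pp$lateral, pp$medial)
  lat <- (pp$lateral - mean(v)) / sd(v)
  A <- branch_features(net, lat)$maps
  C <- dim(A)[3]
  manual <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(C))
    manual <- manual + net$params$head_W[cls + 1, k] * A[, , k]
  manual[manual < 0] <- 0
  expect_equal(cam$lateral_map, manual, tolerance = 1e-10)
})

test_that("maps match the spatially averaged finite-difference gradients", {
  set.seed(54)
  for (i in 1:10) {
    widths <- sample(2:4, 5, replace = TRUE)
    net <- siamese_net(small_spec(widths = as.integer(widths)),
                       seed = 100 + i)
    pp <- random_pair(24, seed = 200 + i)
    cls <- sample(0:4, 1)
    for (br in 1:2) {
      got <- branch_cam(net, pp, class = cls)
      got_map <- if (br == 1) got$lateral_map else got$medial_map
      ref <- cam_fd_reference(net, pp, cls, branch = br)
      if (max(ref) > 0 && max(got_map) > 0) {
        expect_equal(got_map / max(got_map), ref / max(ref),
                     tolerance = 1e-5)
      } else {
        expect_equal(max(got_map), max(ref), tolerance = 1e-8)
      }
    }
  }
})

test_that("ensemble maps are the entrywise sum of member maps", {
  nets <- lapply(1:3, function(s) siamese_net(small_spec(), seed = 60 + s))
  pp <- random_pair(24, seed = 61)
  one <- ensemble_bundle(nets[1])
  expect_equal(ensemble_cam(one, pp, class = 1)$lateral_map,
               branch_cam(nets[[1]], pp, class = 1)$lateral_map)

  trip <- ensemble_bundle(nets[c(2, 2, 2)], seeds = rep(62L, 3))
  expect_equal(ensemble_cam(trip, pp, class = 1)$lateral_map,
               3 * branch_cam(nets[[2]], pp, class = 1)$lateral_map)

  full <- ensemble_cam(ensemble_bundle(nets), pp, class = 4)
  manual <- Reduce(`+`, lapply(nets, function(n)
    branch_cam(n, pp, class = 4)$medial_map))
  expect_equal(full$medial_map, manual)
  expect_true(all(full$lateral_map >= 0))
})

test_that("overlay rendering back-projects, un-flips and normalises", {
  g <- patch_geometry()
  zero <- structure(list(lateral_map = matrix(0, 10, 10),
                         medial_map = matrix(0, 10, 10),
                         target_class = 0L, geometry = g),
                    class = "attention_pair")
  expect_true(all(render_overlay(zero)$heatmap == 0))

  lat_hot <- zero
  lat_hot$lateral_map[1, 1] <- 1
  ov <- render_overlay(lat_hot)
  expect_equal(dim(ov$heatmap), c(300, 300))
  expect_equal(max(ov$heatmap), 1)
  expect_equal(min(ov$heatmap), 0)
  peak <- which(ov$heatmap == 1, arr.ind = TRUE)
  # map (0,0) upsampled sits at the lateral patch's top-left corner
  expect_equal(unname(peak[1, ]), c(101, 1))

  med_hot <- zero
  med_hot$medial_map[1, 1] <- 1
  pk <- which(render_overlay(med_hot)$heatmap == 1, arr.ind = TRUE)
  # stored-frame origin un-flips to the rightmost medial column
  expect_equal(unname(pk[1, ]), c(101, 300))
})

test_that("trained-ensemble attention is reproducible and in range", {
  nets <- lapply(1:2, function(s) siamese_net(small_spec(), seed = 70 + s))
  g <- patch_geometry(resized_px = 60L, S = 24L, K = 18L)
  pp <- random_pair(24, seed = 71, geom = g)
  ov <- render_overlay(ensemble_cam(ensemble_bundle(nets), pp), geom = g)
  expect_true(all(ov$heatmap >= 0 & ov$heatmap <= 1))
  ov2 <- render_overlay(ensemble_cam(ensemble_bundle(nets), pp), geom = g)
  expect_identical(ov$heatmap, ov2$heatmap)
})
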