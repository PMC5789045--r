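tiny_rois <- function(n_per_grade = 2, seed = 400, prefix = "tr") {
  relabel_rois(make_dataset(n_per_grade, seed = seed,
                            split = c(train = 1, val = 0, test = 0))$rois,
               prefix)
}

tiny_cfg <- function(...) {
  kl_train_config(batch_size = 4L, max_iters = 6L, eval_every = 3L,
                  seeds = 21L, ...)
}

test_that("balanced sampler equalises grade frequencies and is seeded", {
  labels <- c(rep(0L, 900), rep(1L, 40), rep(2L, 30), rep(3L, 20),
              rep(4L, 10))
  s1 <- balanced_sampler(labels, seed = 7)
  s2 <- balanced_sampler(labels, seed = 7)
  i1 <- s1(10000)
  expect_identical(i1, s2(10000))              # same seed, same stream
  expect_true(all(i1 >= 1 & i1 <= length(labels)))

  freq <- tabulate(labels[i1] + 1L, nbins = 5) / 10000
  chi <- sum((freq - 0.2)^2 / 0.2) * 10000
  expect_gt(pchisq(chi, df = 4, lower.tail = FALSE), 1e-3)
  expect_true(all(abs(freq - 0.2) < 0.03))

  # drawing must not disturb the surrounding RNG stream
  set.seed(1); a <- runif(3)
  set.seed(1); s1(5); b <- runif(3)
  expect_identical(a, b)

  expect_error(balanced_sampler(c(0L, 1L, 2L, 3L), seed = 1), "grade")
})

test_that("identity augmentation reproduces the plain centre crop", {
  roi <- make_phantom(1, seed = 80)
  img <- truncate_and_rescale(roi)
  set.seed(81)
  out <- augment(img, augment_identity(), crop_mm = 130)
  expect_equal(out$pixels, center_crop_mm(img, 130)$pixels,
               tolerance = 1e-10)
})

test_that("augmentation draws are reproducible and stay in intensity range", {
  roi <- make_phantom(3, seed = 82)
  img <- truncate_and_rescale(roi)
  cfg <- augment_config()
  set.seed(83); a <- augment(img, cfg)
  set.seed(83); b <- augment(img, cfg)
  expect_identical(a$pixels, b$pixels)
  set.seed(84); c <- augment(img, cfg)
  expect_false(identical(a$pixels, c$pixels))
  expect_true(all(is.finite(a$pixels)))
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  expect_equal(dim(a$pixels), c(260, 260))
})

test_that("the direct patch-sampling path matches the module path exactly for identity draws", {
  ds <- kl_dataset(list(make_phantom(2, seed = 85)))
  set.seed(86)
  fast <- ds$get_pair(1, augment_identity())
  slow <- ds$get_pair(1, NULL)
  expect_equal(fast$lateral, slow$lateral, tolerance = 1e-10)
  expect_equal(fast$medial, slow$medial, tolerance = 1e-10)
})

test_that("training is deterministic given a seed and tracks validation metrics", {
  rois <- tiny_rois()
  val <- tiny_rois(1, seed = 401, prefix = "va")
  tr <- kl_dataset(rois)
  va <- kl_dataset(val)
  spec <- branch_spec(N = 4L)

  h1 <- train_one(spec, tr, tiny_cfg(), seed = 21, val = va)
  h2 <- train_one(spec, tr, tiny_cfg(), seed = 21, val = va)
  expect_equal(length(h1$history), 2L)
  expect_identical(vapply(h1$history, `[[`, 0, "val_loss"),
                   vapply(h2$history, `[[`, 0, "val_loss"))
  expect_identical(vapply(h1$history, `[[`, 0, "train_loss"),
                   vapply(h2$history, `[[`, 0, "train_loss"))
  expect_equal(vapply(h1$history, `[[`, 0, "iteration"), c(3, 6))

  h3 <- train_one(spec, tr, tiny_cfg(), seed = 22, val = va)
  expect_false(identical(h1$history[[2]]$val_loss, h3$history[[2]]$val_loss))

  expect_error(train_one(spec, tr, tiny_cfg(), seed = 21, val = tr),
               "share ids")
})

test_that("zero learning rate freezes the model across snapshots", {
  rois <- tiny_rois()
  val <- tiny_rois(1, seed = 402, prefix = "va")
  h <- train_one(branch_spec(N = 4L), kl_dataset(rois), tiny_cfg(lr = 0),
                 seed = 21, val = kl_dataset(val))
  # every learnable parameter is untouched across snapshots (the
  # batch-normalisation *running statistics* still track batch moments,
  # so they are excluded from this identity)
  expect_identical(h$history[[1]]$snapshot$params,
                   h$history[[2]]$snapshot$params)
  init <- siamese_net(branch_spec(N = 4L), seed = 21)
  expect_identical(h$history[[2]]$snapshot$params$head_W,
                   init$params$head_W)
})

test_that("snapshot selection maximises validation kappa with earliest-tie rule", {
  fake <- function(it, kap) list(iteration = it, val_kappa = kap)
  hist <- list(fake(100, 0.1), fake(200, 0.5), fake(300, 0.9))
  expect_equal(select_snapshot(hist)$iteration, 300)  # improving -> last
  hist2 <- list(fake(100, 0.7), fake(200, 0.7), fake(300, 0.2))
  expect_equal(select_snapshot(hist2)$iteration, 100) # tie -> earliest
  expect_equal(select_snapshot(list(fake(50, 0.3)))$iteration, 50)
  expect_error(select_snapshot(list()), "empty")
})

test_that("bundle training records one member per seed and stays shared", {
  rois <- tiny_rois()
  val <- tiny_rois(1, seed = 403, prefix = "va")
  cfg <- kl_train_config(batch_size = 4L, max_iters = 4L, eval_every = 2L,
                         seeds = c(21L, 84L))
  fit <- train_bundle(branch_spec(N = 4L), kl_dataset(rois),
                      kl_dataset(val), cfg)
  expect_length(fit$bundle$members, 2L)
  expect_equal(fit$bundle$seeds, c(21L, 84L))

  # weight sharing survives optimisation: a symmetric pair still yields
  # identical branch descriptors from the trained member
  net <- fit$bundle$members[[1]]
  pp <- kl_dataset(val)$get_pair(1)
  pp$medial <- pp$lateral
  fw <- siamese_forward(net, list(pp), training = FALSE)
  C <- nrow(fw$feat) %/% 2
  expect_equal(fw$feat[seq_len(C), 1], fw$feat[C + seq_len(C), 1])
  # and the trained parameters differ from initialisation
  init <- siamese_net(branch_spec(N = 4L), seed = 21)
  expect_false(identical(net$params$conv[[1]], init$params$conv[[1]]))
})

test_that("training configuration validates its ranges", {
  expect_error(kl_train_config(lr = -1), "lr")
  expect_error(kl_train_config(max_iters = 10, eval_every = 20),
               "eval_every")
  expect_error(augment_config(rotation_deg = c(5, 10)), "identity")
  expect_error(augment_config(contrast = c(1.1, 1.5)), "identity")
})
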