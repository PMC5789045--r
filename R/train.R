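#' Augmentation configuration
#'
#' Ranges for the five on-the-fly augmentations; every range contains the
#' identity transform so degenerate ranges reproduce the input exactly.
#' Defaults: rotation +-10 degrees, brightness +-30 (8-bit units),
#' contrast x\[0.8, 1.2\] about the image mean, jitter +-15 px, gamma
#' \[0.8, 1.25\].
#'
#' @param rotation_deg,brightness,contrast,jitter_px,gamma length-2 ranges.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_deg = c(-10, 10),
                           brightness = c(-30, 30),
                           contrast = c(0.8, 1.2),
                           jitter_px = c(-15, 15),
                           gamma = c(0.8, 1.25)) {
  chk <- function(r, id, what) {
    if (length(r) != 2 || r[1] > r[2]) stop("invalid range for ", what)
    if (id < r[1] || id > r[2])
      stop("the ", what, " range must contain the identity value ", id)
    r
  }
  structure(list(rotation_deg = chk(rotation_deg, 0, "rotation"),
                 brightness = chk(brightness, 0, "brightness"),
                 contrast = chk(contrast, 1, "contrast"),
                 jitter_px = chk(jitter_px, 0, "jitter"),
                 gamma = chk(gamma, 1, "gamma")),
            class = "augment_config")
}

#' Identity augmentation (all ranges degenerate)
#' @return An `augment_config` whose every draw is the identity.
#' @export
augment_identity <- function() {
  augment_config(c(0, 0), c(0, 0), c(1, 1), c(0, 0), c(1, 1))
}

# One random draw of augmentation parameters plus the order in which the
# five operations were drawn. Shared by augment() and the direct
# patch-sampling path so both consume the RNG identically.
.draw_augment_params <- function(cfg) {
  draw <- function(r) stats::runif(1, r[1], r[2])
  list(angle = draw(cfg$rotation_deg), bright = draw(cfg$brightness),
       contr = draw(cfg$contrast), jx = draw(cfg$jitter_px),
       jy = draw(cfg$jitter_px), gam = draw(cfg$gamma), ord = sample(5L))
}

# Compose the geometric operations (in drawn relative order) into the
# forward affine map of the augmented frame.
.augment_geom <- function(par, w, h) {
  G <- affine_identity()
  for (op in par$ord) {
    if (op == 1L) G <- affine_rotate(par$angle, (w - 1) / 2, (h - 1) / 2) %*% G
    if (op == 4L) G <- affine_translate(par$jx, par$jy) %*% G
  }
  G
}

# Apply the intensity operations in their drawn relative order, then clip.
# Contrast pivots about the 8-bit midpoint so the operation is pointwise.
.augment_intensity <- function(v, par) {
  for (op in par$ord) {
    if (op == 2L) v <- v + par$bright
    if (op == 3L) v <- 127.5 + (v - 127.5) * par$contr
    if (op == 5L) v <- 255 * (pmin(pmax(v, 0), 255) / 255)^par$gam
  }
  pmin(pmax(v, 0), 255)
}

#' Randomly augment a source image and take the physical crop
#'
#' Draws rotation, brightness, contrast, jitter and gamma from `cfg` and
#' applies them in a randomly permuted order, then takes the centred
#' `crop_mm` crop. The two geometric operations (rotation about the image
#' centre, translation jitter) are composed — in their drawn relative
#' order — into a single affine map so the output is produced by one
#' resampling pass; the three intensity operations are composed as
#' functions in their drawn relative order and applied afterwards, with a
#' final clip to \[0, 255\]. Samples falling outside the source image are
#' clamped to the nearest edge pixel. Uses the current RNG state, so a
#' seeded caller gets reproducible draws.
#'
#' @param img a [knee_norm()] image.
#' @param cfg an [augment_config()].
#' @param crop_mm physical side of the final centre crop (default 130).
#' @return A [knee_norm()] image of the cropped, augmented region.
#' @export
augment <- function(img, cfg = augment_config(), crop_mm = 130) {
  stopifnot(inherits(img, "knee_norm"), inherits(cfg, "augment_config"))
  par <- .draw_augment_params(cfg)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  G <- .augment_geom(par, w, h)
  t_px <- round(crop_mm / img$spacing_mm)
  if (t_px > h || t_px > w) stop("crop exceeds image size")
  top <- (h - t_px) %/% 2
  left <- (w - t_px) %/% 2
  # output crop pixel -> augmented-frame pixel -> source pixel
  A <- solve(G) %*% affine_translate(left, top)
  out <- warp_affine(img$pixels, A, t_px, t_px)
  out <- .augment_intensity(out, par)
  knee_norm(out, img$spacing_mm, img$kl_grade, img$source_id)
}

# 0-based coordinates of every stored-patch pixel in the resized-image
# frame, column-major (row fastest), medial already flip-corrected.
.patch_grids <- function(geom) {
  S <- geom$S
  idx <- 0:(S - 1)
  list(
    lat_x = rep(geom$lateral_origin["x"] + idx, each = S),
    lat_y = rep(geom$lateral_origin["y"] + idx, times = S),
    med_x = rep(geom$medial_origin["x"] + (S - 1) - idx, each = S),
    med_y = rep(geom$medial_origin["y"] + idx, times = S)
  )
}

# Fast equivalent of augment() + resize_to_grid() + extract_pair(): the
# crop, the grid resize and the random geometric transform compose into a
# single affine map, so only the two SxS patch grids are ever resampled.
# With an identity geometric draw this is exactly the step-by-step path;
# with rotation/jitter it resamples the source once instead of twice
# (warp, then resize), which sharpens edges slightly relative to the
# sequential operations.
.augmented_pair <- function(img, cfg, crop_mm, geom, grids, source_id = "") {
  par <- .draw_augment_params(cfg)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  G <- .augment_geom(par, w, h)
  t_px <- round(crop_mm / img$spacing_mm)
  top <- (h - t_px) %/% 2
  left <- (w - t_px) %/% 2
  sc <- (t_px - 1) / (geom$resized_px - 1)
  Sm <- diag(c(sc, sc, 1))
  A <- solve(G) %*% affine_translate(left, top) %*% Sm
  S <- geom$S
  sample_patch <- function(gx, gy) {
    sx <- A[1, 1] * gx + A[1, 2] * gy + A[1, 3]
    sy <- A[2, 1] * gx + A[2, 2] * gy + A[2, 3]
    matrix(.augment_intensity(bilinear_sample(img$pixels, sx, sy), par), S, S)
  }
  structure(list(lateral = sample_patch(grids$lat_x, grids$lat_y),
                 medial = sample_patch(grids$med_x, grids$med_y),
                 geometry = geom, source_id = as.character(source_id)),
            class = "patch_pair")
}

#' Class-balancing index stream
#'
#' Oversampling with bootstrapping: an infinite stream of training indices
#' in which each of the five KL grades has equal expected frequency,
#' regardless of the empirical class distribution. Draws are with
#' replacement (first a grade uniformly, then a case uniformly within the
#' grade). The stream carries its own RNG state, so interleaving it with
#' other random draws does not perturb it and the same seed always yields
#' the same stream.
#'
#' @param labels integer vector of KL grades for the training cases.
#' @param seed stream seed.
#' @param n_grades number of grades (default 5).
#' @return A function `draw(n)` returning the next `n` indices.
#' @export
balanced_sampler <- function(labels, seed, n_grades = 5L) {
  present <- sort(unique(labels))
  absent <- setdiff(0:(n_grades - 1L), present)
  if (length(absent))
    stop("cannot balance: no cases for grade(s) ",
         paste(absent, collapse = ", "))
  by_class <- split(seq_along(labels), factor(labels, levels = 0:(n_grades - 1L)))
  sizes <- lengths(by_class)
  flat <- unlist(by_class, use.names = FALSE)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    g <- sample.int(n_grades, n, replace = TRUE)
    pos <- ceiling(stats::runif(n) * sizes[g])
    pos[pos < 1L] <- 1L
    idx <- flat[offs[g] + pos]
    state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    idx
  }
}

#' Training configuration
#'
#' The optimisation recipe: Adam with cross-entropy loss, L2 weight decay,
#' periodic validation, one snapshot per evaluation. Defaults mirror the
#' full-scale recipe (learning rate 1e-2, weight decay 1e-4, dropout 0.2,
#' batch 64, seeds 21/42/84, evaluation every 500 of 50,000 iterations);
#' `max_iters`, `eval_every` and `batch_size` scale down for desk-scale
#' runs.
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param batch_size pairs per iteration.
#' @param max_iters total optimisation iterations.
#' @param eval_every validate (and snapshot) every this many iterations.
#' @param seeds one training seed per ensemble member.
#' @param dropout dropout rate after concatenation.
#' @param augmentation an [augment_config()].
#' @return An object of class `kl_train_config`.
#' @export
kl_train_config <- function(lr = 1e-2, weight_decay = 1e-4, batch_size = 64L,
                            max_iters = 50000L, eval_every = 500L,
                            seeds = c(21L, 42L, 84L), dropout = 0.2,
                            augmentation = augment_config()) {
  stopifnot(lr >= 0, weight_decay >= 0, batch_size >= 1, max_iters >= 1,
            eval_every >= 1, eval_every <= max_iters, length(seeds) >= 1,
            dropout >= 0, dropout < 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_iters = as.integer(max_iters),
                 eval_every = as.integer(eval_every),
                 seeds = as.integer(seeds), dropout = dropout,
                 augmentation = augmentation),
            class = "kl_train_config")
}

# ---- Adam ------------------------------------------------------------------

# Flatten the learnable parameters into a named list of numeric objects so
# one optimiser loop serves convolutions, BN and the head alike.
.param_list <- function(params) {
  out <- list()
  for (l in 1:5) {
    out[[paste0("conv", l)]] <- params$conv[[l]]
    out[[paste0("bn_g", l)]] <- params$bn[[l]]$gamma
    out[[paste0("bn_b", l)]] <- params$bn[[l]]$beta
  }
  out$head_W <- params$head_W
  out$head_b <- params$head_b
  out
}

.grad_list <- function(grads, head_dW, head_db) {
  out <- list()
  for (l in 1:5) {
    out[[paste0("conv", l)]] <- grads$conv[[l]]
    out[[paste0("bn_g", l)]] <- grads$bn[[l]]$gamma
    out[[paste0("bn_b", l)]] <- grads$bn[[l]]$beta
  }
  out$head_W <- head_dW
  out$head_b <- head_db
  out
}

.params_from_list <- function(pl) {
  params <- list(conv = vector("list", 5), bn = vector("list", 5))
  for (l in 1:5) {
    params$conv[[l]] <- pl[[paste0("conv", l)]]
    params$bn[[l]] <- list(gamma = pl[[paste0("bn_g", l)]],
                           beta = pl[[paste0("bn_b", l)]])
  }
  params$head_W <- pl$head_W
  params$head_b <- pl$head_b
  params
}

adam_init <- function(pl) {
  list(t = 0L,
       m = lapply(pl, function(p) p * 0),
       v = lapply(pl, function(p) p * 0))
}

adam_step <- function(pl, gl, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(pl)) {
    g <- gl[[k]] + weight_decay * pl[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    pl[[k]] <- pl[[k]] - lr * (opt$m[[k]] / bc1) /
      (sqrt(opt$v[[k]] / bc2) + eps)
  }
  list(pl = pl, opt = opt)
}

# ---- Dataset wrapper -------------------------------------------------------

#' Prepare a training dataset from raw ROIs
#'
#' Applies the deterministic part of the pipeline once (left-knee flip,
#' percentile truncation to 8-bit) and keeps the normalised source images;
#' patch pairs are produced per draw, with or without augmentation, by
#' cropping to `crop_mm`, resizing to the geometry's grid and extracting
#' the symmetric pair.
#'
#' @param rois list of [knee_roi()] with `kl_grade` set.
#' @param geometry a [patch_geometry()].
#' @param lo_pct,hi_pct truncation percentiles.
#' @param crop_mm physical crop applied after augmentation.
#' @return An object of class `kl_dataset` with `$get_pair(i, augment_cfg)`.
#' @export
kl_dataset <- function(rois, geometry = patch_geometry(), lo_pct = 5,
                       hi_pct = 99, crop_mm = 130) {
  labels <- vapply(rois, function(r) r$kl_grade, integer(1))
  if (anyNA(labels)) stop("all training ROIs must carry a KL grade")
  imgs <- lapply(rois, function(r)
    truncate_and_rescale(flip_if_left(r), lo_pct, hi_pct))
  ids <- vapply(rois, function(r) r$source_id, character(1))
  grids <- .patch_grids(geometry)
  get_pair <- function(i, augment_cfg = NULL) {
    im <- imgs[[i]]
    if (!is.null(augment_cfg))
      return(.augmented_pair(im, augment_cfg, crop_mm, geometry, grids,
                             source_id = ids[i]))
    cropped <- center_crop_mm(im, crop_mm)
    extract_pair(resize_to_grid(cropped, geometry$resized_px), geometry,
                 source_id = ids[i])
  }
  structure(list(images = imgs, labels = labels, ids = ids,
                 geometry = geometry, crop_mm = crop_mm,
                 get_pair = get_pair, n = length(rois)),
            class = "kl_dataset")
}

#' @export
print.kl_dataset <- function(x, ...) {
  cat(sprintf("<kl_dataset> %d knees; grades: %s\n", x$n,
              paste(sprintf("KL%d:%d", 0:4,
                            tabulate(factor(x$labels, 0:4))), collapse = " ")))
  invisible(x)
}

# ---- Training loop ---------------------------------------------------------

#' Train one network from one seed
#'
#' Optimises the shared-weight network with Adam on cross-entropy plus L2
#' weight decay: per iteration a class-balanced bootstrap batch is drawn,
#' every image is augmented on the fly, and every `eval_every` iterations
#' the model is evaluated on the validation pairs (quadratic kappa,
#' balanced accuracy, loss) and a parameter snapshot is stored. The whole
#' run — weight initialisation, sampling, augmentation, dropout — is
#' driven by `seed`, so identical calls give identical histories.
#'
#' @param spec a [branch_spec()].
#' @param data a [kl_dataset()] of training knees.
#' @param cfg a [kl_train_config()].
#' @param seed training seed for this member.
#' @param val a [kl_dataset()] of validation knees (disjoint ids).
#' @return A `train_history`: list of snapshots, each with `iteration`,
#'   `val_kappa`, `val_acc`, `val_loss`, `train_loss` and the parameters.
#' @export
train_one <- function(spec, data, cfg, seed, val) {
  stopifnot(inherits(data, "kl_dataset"), inherits(val, "kl_dataset"))
  if (length(intersect(data$ids, val$ids)))
    stop("training and validation sets share ids")
  net <- siamese_net(spec, dropout = cfg$dropout, seed = seed)
  sampler <- balanced_sampler(data$labels, seed = seed)
  set.seed(seed + 1L)   # augmentation / dropout stream

  val_pairs <- lapply(seq_len(val$n), function(i) val$get_pair(i))
  # validation tensors prepared once, in chunks to bound engine memory
  val_groups <- split(seq_len(val$n), ceiling(seq_len(val$n) / 64))
  val_X <- lapply(val_groups, function(ix) pairs_to_tensor(val_pairs[ix]))
  val_y <- val$labels

  pl <- .param_list(net$params)
  opt <- adam_init(pl)
  history <- list()
  loss_acc <- 0

  evaluate <- function(net) {
    logits <- do.call(cbind, lapply(val_X, function(X)
      siamese_forward(net, X, training = FALSE)$logits))
    ce <- cross_entropy(logits, val_y)
    pred <- max.col(t(logits), "first") - 1L
    kap <- tryCatch(quadratic_kappa(val_y, pred), error = function(e) NA_real_)
    acc <- avg_multiclass_accuracy(confusion_matrix(val_y, pred))
    list(kappa = kap, acc = as.numeric(acc), loss = ce$loss)
  }

  for (it in seq_len(cfg$max_iters)) {
    idx <- sampler(cfg$batch_size)
    pairs <- lapply(idx, function(i) data$get_pair(i, cfg$augmentation))
    X <- pairs_to_tensor(pairs)
    y <- data$labels[idx]

    fw <- siamese_forward(net, X, training = TRUE, keep_cache = TRUE)
    net$state <- fw$branch$new_state
    ce <- cross_entropy(fw$logits, y)
    if (!is.finite(ce$loss))
      stop("training diverged: non-finite loss at iteration ", it)
    loss_acc <- loss_acc + ce$loss

    # head backward
    dlogits <- ce$dlogits                       # 5 x B
    dW_head <- dlogits %*% t(fw$feat_d)
    db_head <- rowSums(dlogits)
    dfeat <- t(net$params$head_W) %*% dlogits
    if (!is.null(fw$mask)) dfeat <- dfeat * fw$mask
    C <- nrow(dfeat) %/% 2L
    dPooled <- cbind(dfeat[seq_len(C), , drop = FALSE],
                     dfeat[C + seq_len(C), , drop = FALSE])
    grads <- branch_backward(net, fw$branch, dPooled)

    st <- adam_step(pl, .grad_list(grads, dW_head, db_head), opt,
                    cfg$lr, cfg$weight_decay)
    pl <- st$pl
    opt <- st$opt
    net$params <- .params_from_list(pl)

    if (it %% cfg$eval_every == 0L) {
      ev <- evaluate(net)
      history[[length(history) + 1L]] <- list(
        iteration = it, seed = seed,
        val_kappa = ev$kappa, val_acc = ev$acc, val_loss = ev$loss,
        train_loss = loss_acc / cfg$eval_every,
        snapshot = snapshot_params(net))
      loss_acc <- 0
    }
  }
  structure(list(history = history, spec = spec, seed = seed,
                 dropout = cfg$dropout),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> seed %d, %d snapshots\n", x$seed,
              length(x$history)))
  for (h in x$history)
    cat(sprintf("  iter %6d: val kappa %6.3f, bal acc %5.3f, val loss %.4f\n",
                h$iteration, h$val_kappa, h$val_acc, h$val_loss))
  invisible(x)
}

#' Select the best validation snapshot
#'
#' Returns the snapshot with the highest validation quadratic kappa; ties
#' (and all-NA kappa histories) resolve to the earliest iteration.
#'
#' @param hist a `train_history` from [train_one()].
#' @return The selected snapshot element.
#' @export
select_snapshot <- function(hist) {
  h <- if (inherits(hist, "train_history")) hist$history else hist
  if (!length(h)) stop("empty training history")
  kap <- vapply(h, function(s)
    ifelse(is.na(s$val_kappa), -Inf, s$val_kappa), numeric(1))
  h[[which.max(kap)]]   # which.max takes the earliest of tied maxima
}

#' Train a full ensemble
#'
#' Runs [train_one()] once per seed in `cfg$seeds`, selects each run's best
#' validation snapshot and assembles the members into an
#' [ensemble_bundle()].
#'
#' @param spec a [branch_spec()].
#' @param data,val training and validation [kl_dataset()]s.
#' @param cfg a [kl_train_config()].
#' @param verbose print per-seed progress.
#' @return A list with `bundle` (the [ensemble_bundle()]) and `histories`.
#' @export
train_bundle <- function(spec, data, val, cfg = kl_train_config(),
                         verbose = FALSE) {
  histories <- list()
  members <- list()
  for (s in cfg$seeds) {
    if (verbose) message("training member with seed ", s)
    hist <- train_one(spec, data, cfg, seed = s, val = val)
    best <- select_snapshot(hist)
    net <- siamese_net(spec, dropout = cfg$dropout, seed = s)
    net <- restore_params(net, best$snapshot)
    members[[length(members) + 1L]] <- net
    histories[[as.character(s)]] <- hist
    if (verbose)
      message(sprintf("  best snapshot: iter %d, val kappa %.3f",
                      best$iteration, best$val_kappa))
  }
  list(bundle = ensemble_bundle(members, cfg$seeds), histories = histories)
}
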