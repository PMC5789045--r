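#' Specification of one Siamese branch
#'
#' Describes the convolutional stack shared by the two branches: exactly
#' five 3x3 valid (unpadded) convolutions, each of which strictly reduces
#' the spatial size, the first with stride 2, with 2x2 max-pooling after
#' selected layers. With the defaults (`input_px = 128`) the spatial trace
#' is 128 -> 63 -> 61 -> 30 (pool) -> 28 -> 14 (pool) -> 12 -> 10, so each
#' branch ends in 10x10 activation maps before global average pooling —
#' deliberately higher resolution than typical deep classifiers, which is
#' what makes the attention maps sharp.
#'
#' Channel widths default to `c(N/2, N/2, N, N, N)` with base width
#' `N = 64`, giving a `2N`-dimensional concatenated descriptor.
#'
#' @param N base channel width (default 64).
#' @param widths integer vector of 5 output channel counts per convolution.
#' @param strides integer vector of 5 convolution strides (first 2, rest 1).
#' @param pool_after indices of convolutions followed by 2x2 max-pooling.
#' @param input_px expected square input size (default 128).
#' @return An object of class `branch_spec` including the validated
#'   spatial `trace`.
#' @export
branch_spec <- function(N = 64L,
                        widths = c(N %/% 2, N %/% 2, N, N, N),
                        strides = c(2L, 1L, 1L, 1L, 1L),
                        pool_after = c(2L, 3L),
                        input_px = 128L) {
  if (length(widths) != 5)
    stop("a branch has exactly five convolution layers; got ", length(widths))
  if (length(strides) != 5) stop("`strides` must have length 5")
  if (strides[1] != 2L || any(strides[-1] != 1L))
    stop("the first convolution has stride 2 and all others stride 1")
  if (any(widths < 1)) stop("channel widths must be positive")
  trace <- spatial_trace(input_px, strides, pool_after)
  structure(list(N = as.integer(N), widths = as.integer(widths),
                 strides = as.integer(strides),
                 pool_after = as.integer(pool_after),
                 input_px = as.integer(input_px), trace = trace),
            class = "branch_spec")
}

# Valid-convolution arithmetic: floor((n - 3)/s) + 1 per conv, floor(n/2)
# per pool. Errors (with the offending layer index) if the trace collapses.
spatial_trace <- function(input_px, strides = c(2L, 1L, 1L, 1L, 1L),
                          pool_after = c(2L, 3L)) {
  n <- as.integer(input_px)
  trace <- n
  for (l in seq_along(strides)) {
    n <- (n - 3L) %/% strides[l] + 1L
    if (n < 1L)
      stop("spatial size collapses to ", n, " at convolution ", l)
    trace <- c(trace, n)
    if (l %in% pool_after) {
      n <- n %/% 2L
      if (n < 1L)
        stop("spatial size collapses to ", n, " at the pool after convolution ", l)
      trace <- c(trace, n)
    }
  }
  trace
}

#' Build the shared-weight Siamese network
#'
#' Constructs the two-branch network: each branch is the Conv-BN-ReLU stack
#' of `spec` (with 2x2 max-pools at `spec$pool_after`) ending in global
#' average pooling; the two pooled descriptors are concatenated, passed
#' through dropout and a final linear layer producing one unnormalised
#' score per KL grade. Both branch passes read literally the same parameter
#' storage — the branches are a single set of weights applied twice, which
#' halves the branch parameter count relative to an unshared twin.
#'
#' @param spec a [branch_spec()].
#' @param dropout dropout rate applied after concatenation (default 0.2).
#' @param n_classes number of output grades (default 5).
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `siamese_net`.
#' @export
siamese_net <- function(spec = branch_spec(), dropout = 0.2, n_classes = 5L,
                        seed = 42L) {
  stopifnot(inherits(spec, "branch_spec"))
  set.seed(seed)
  c_in <- c(1L, spec$widths[-5])
  conv <- lapply(1:5, function(l) {
    fan_in <- 9L * c_in[l]
    matrix(stats::rnorm(fan_in * spec$widths[l], sd = sqrt(2 / fan_in)),
           fan_in, spec$widths[l])
  })
  bn <- lapply(spec$widths, function(cw) {
    list(gamma = rep(1, cw), beta = rep(0, cw))
  })
  C <- spec$widths[5]
  head_in <- 2L * C
  params <- list(
    conv = conv, bn = bn,
    head_W = matrix(stats::rnorm(n_classes * head_in,
                                 sd = sqrt(2 / head_in)),
                    n_classes, head_in),
    head_b = rep(0, n_classes)
  )
  state <- list(
    run_mean = lapply(spec$widths, function(cw) rep(0, cw)),
    run_var = lapply(spec$widths, function(cw) rep(1, cw))
  )
  structure(list(spec = spec, params = params, state = state,
                 dropout = dropout, n_classes = as.integer(n_classes),
                 descriptor_dim = head_in, seed = as.integer(seed)),
            class = "siamese_net")
}

#' @export
print.siamese_net <- function(x, ...) {
  cat(sprintf(
    "<siamese_net> shared branch widths [%s], strides [%s], pools after {%s}\n",
    paste(x$spec$widths, collapse = ", "),
    paste(x$spec$strides, collapse = ", "),
    paste(x$spec$pool_after, collapse = ", ")))
  cat(sprintf("  input %dx%d -> trace %s -> GAP -> concat(%d) -> dropout %.2g -> %d classes\n",
              x$spec$input_px, x$spec$input_px,
              paste(x$spec$trace, collapse = " -> "), x$descriptor_dim,
              x$dropout, x$n_classes))
  cat(sprintf("  learnable parameters: %d (unshared twin: %d)\n",
              parameter_count(x, shared = TRUE),
              parameter_count(x, shared = FALSE)))
  invisible(x)
}

# One pass of the shared branch over a stacked batch (H, W, B', 1); in the
# Siamese forward B' = 2B with the lateral patches first. Returns the
# pooled descriptors plus (optionally) all layer caches for backprop, the
# pre-GAP activation maps, and — in training mode — the updated
# batch-normalisation running statistics (`new_state`), which the caller
# must write back into the network (R objects are copied on modify).
branch_pass <- function(net, X, training = FALSE, keep_cache = FALSE) {
  p <- net$params
  s <- net$spec
  caches <- if (keep_cache) vector("list", 5) else NULL
  new_state <- net$state
  for (l in 1:5) {
    conv_in <- X
    Yc <- conv_forward(X, p$conv[[l]], s$strides[l])
    bf <- bn_forward(Yc, p$bn[[l]]$gamma, p$bn[[l]]$beta,
                     net$state$run_mean[[l]], net$state$run_var[[l]],
                     training = training)
    if (training) {
      new_state$run_mean[[l]] <- bf$run_mean
      new_state$run_var[[l]] <- bf$run_var
    }
    Y <- relu_forward(bf$Y)
    pf <- NULL
    if (l %in% s$pool_after) {
      pf <- maxpool_forward(Y)
      out <- pf$Y
    } else {
      out <- Y
    }
    if (keep_cache)
      caches[[l]] <- list(conv_in = conv_in, bn = bf, relu_out = Y,
                          pool = pf)
    X <- out
  }
  pooled <- gap_forward(X)
  list(pooled = pooled, maps = X, caches = caches, map_dim = dim(X),
       new_state = new_state)
}

# Gradient flow mirror of branch_pass. dPooled is (C, B').
branch_backward <- function(net, fwd, dPooled) {
  p <- net$params
  s <- net$spec
  grads <- list(conv = vector("list", 5), bn = vector("list", 5))
  dX <- gap_backward(dPooled, fwd$map_dim)
  for (l in 5:1) {
    cc <- fwd$caches[[l]]
    if (!is.null(cc$pool)) dX <- maxpool_backward(dX, cc$pool)
    dX <- relu_backward(dX, cc$relu_out)
    dYm <- dX
    dim(dYm) <- c(prod(dim(dX)[1:3]), dim(dX)[4])
    grads$bn[[l]] <- list(gamma = colSums(dYm * cc$bn$xhat),
                          beta = colSums(dYm))
    dXb <- bn_backward(dX, cc$bn, p$bn[[l]]$gamma)
    cb <- conv_backward(dXb, cc$conv_in, p$conv[[l]], s$strides[l])
    grads$conv[[l]] <- cb$dW
    dX <- cb$dX
  }
  grads
}

# Stack a list of patch_pairs into the branch input array (S, S, 2B, 1),
# lateral patches occupying slots 1..B. Per-image standardisation to zero
# mean / unit variance happens here, over both patches jointly.
pairs_to_tensor <- function(pairs, standardize = TRUE) {
  B <- length(pairs)
  S <- nrow(pairs[[1]]$lateral)
  X <- array(0, c(S, S, 2L * B, 1L))
  for (b in seq_len(B)) {
    lat <- pairs[[b]]$lateral
    med <- pairs[[b]]$medial
    if (standardize) {
      v <- c(lat, med)
      mu <- mean(v)
      sd <- stats::sd(v)
      if (sd < 1e-8) sd <- 1
      lat <- (lat - mu) / sd
      med <- (med - mu) / sd
    }
    X[, , b, 1] <- lat
    X[, , B + b, 1] <- med
  }
  X
}

# Full Siamese forward over a batch of pairs. Returns logits (n_classes x B)
# plus caches when training. Dropout uses inverted scaling so evaluation
# mode is the identity.
siamese_forward <- function(net, pairs, training = FALSE,
                            keep_cache = FALSE) {
  if (inherits(pairs, "patch_pair")) pairs <- list(pairs)
  X <- if (is.array(pairs)) pairs else pairs_to_tensor(pairs)
  B <- dim(X)[3] %/% 2L
  br <- branch_pass(net, X, training = training, keep_cache = keep_cache)
  feat <- rbind(br$pooled[, seq_len(B), drop = FALSE],
                br$pooled[, B + seq_len(B), drop = FALSE])
  mask <- NULL
  if (training && net$dropout > 0) {
    mask <- matrix(stats::runif(length(feat)) >= net$dropout, nrow(feat)) /
      (1 - net$dropout)
    feat_d <- feat * mask
  } else {
    feat_d <- feat
  }
  logits <- net$params$head_W %*% feat_d +
    matrix(net$params$head_b, net$n_classes, B)
  list(logits = logits, feat = feat, feat_d = feat_d, mask = mask,
       branch = br, B = B)
}

#' Forward pass: KL-grade scores for a patch pair
#'
#' Runs the pair through the shared branch twice (lateral, then flipped
#' medial), concatenates the two pooled descriptors and applies the linear
#' head. Evaluation mode: dropout off, batch normalisation using running
#' statistics, so repeated calls are bitwise identical.
#'
#' @param net a [siamese_net()].
#' @param pair a `patch_pair` (or list of them).
#' @return Numeric vector of `n_classes` unnormalised scores (or a matrix
#'   with one column per pair).
#' @export
siamese_logits <- function(net, pair) {
  single <- inherits(pair, "patch_pair")
  S <- net$spec$input_px
  ps <- if (single) list(pair) else pair
  if (nrow(ps[[1]]$lateral) != S)
    stop(sprintf("patch size %d does not match the network input size %d",
                 nrow(ps[[1]]$lateral), S))
  out <- siamese_forward(net, ps, training = FALSE)$logits
  if (single) drop(out) else out
}

#' Pre-GAP activation maps and pooled descriptor of one branch
#'
#' Exposes the penultimate (post-ReLU, pre-global-average-pooling)
#' activation maps of the shared branch for a single patch, together with
#' the pooled descriptor — the quantities the attention module works on.
#' With the default specification and a 128x128 input the maps are 10x10.
#'
#' @param net a [siamese_net()].
#' @param patch an S x S intensity matrix (already standardised or raw).
#' @param standardize standardise the patch to zero mean/unit variance first.
#' @return A list with `maps` (array H x W x C) and `pooled` (length-C
#'   vector of spatial means).
#' @export
branch_features <- function(net, patch, standardize = FALSE) {
  if (standardize) {
    sdv <- stats::sd(patch)
    patch <- (patch - mean(patch)) / (if (sdv < 1e-8) 1 else sdv)
  }
  X <- array(patch, c(nrow(patch), ncol(patch), 1, 1))
  br <- branch_pass(net, X, training = FALSE)
  list(maps = array(br$maps, dim(br$maps)[c(1, 2, 4)]),
       pooled = drop(br$pooled))
}

#' Count learnable parameters
#'
#' Counts convolution kernels, batch-normalisation scale/shift and head
#' weights. With `shared = FALSE` the hypothetical unshared twin (two
#' independent branches, identical head) is counted instead, quantifying
#' the saving bought by anatomical weight sharing: the branch cost exactly
#' halves.
#'
#' @param net a [siamese_net()].
#' @param shared count the shared model (default) or its unshared twin.
#' @return Integer parameter count.
#' @export
parameter_count <- function(net, shared = TRUE) {
  p <- net$params
  branch <- sum(vapply(p$conv, length, numeric(1))) +
    sum(vapply(p$bn, function(x) length(x$gamma) + length(x$beta),
               numeric(1)))
  head <- length(p$head_W) + length(p$head_b)
  as.integer(if (shared) branch + head else 2L * branch + head)
}

# Deep copy of the learnable parameters + BN running statistics, used for
# snapshots and checkpoints (plain lists of numerics, so a copy is a copy).
snapshot_params <- function(net) {
  list(params = net$params, state = net$state)
}

restore_params <- function(net, snap) {
  net$params <- snap$params
  net$state <- snap$state
  net
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the branch and head
#' weights, the branch specification, batch-normalisation running
#' statistics, the training seed and a schema version.
#'
#' @param net a [siamese_net()].
#' @param path file path (`.rds`).
#' @return `load_checkpoint()` returns a [siamese_net()].
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(schema = "kneekl-checkpoint-1",
               spec = net$spec, params = net$params, state = net$state,
               dropout = net$dropout, n_classes = net$n_classes,
               seed = net$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "kneekl-checkpoint-1"))
    stop("unrecognised checkpoint schema: ", ck$schema)
  net <- siamese_net(ck$spec, ck$dropout, ck$n_classes, seed = ck$seed)
  net$params <- ck$params
  net$state <- ck$state
  net
}
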