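#' KL-grade probability distribution
#'
#' Validated probability vector over KL grades 0..4.
#'
#' @param probs length-5 non-negative numeric vector summing to 1
#'   (within 1e-6).
#' @return An object of class `grade_distribution`.
#' @export
grade_distribution <- function(probs) {
  if (length(probs) != 5) stop("a grade distribution has 5 entries (KL 0..4)")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-6) stop("probabilities must sum to 1")
  structure(as.numeric(probs), names = paste0("KL", 0:4),
            class = "grade_distribution")
}

#' @export
print.grade_distribution <- function(x, ...) {
  cat("<grade_distribution>\n")
  print(round(unclass(x), 4))
  cat(sprintf("  argmax: KL-%d, P(radiographic OA) = %.4f\n",
              which.max(x) - 1L, oa_probability(x)))
  invisible(x)
}

#' Bundle of independently trained ensemble members
#'
#' Holds M trained networks (snapshots selected on validation data) that
#' share one branch specification, plus the seeds that initialised them.
#' Mimics a committee of readers: each member grades independently and the
#' ensemble fuses their pre-softmax scores.
#'
#' @param members list of [siamese_net()] objects.
#' @param seeds integer vector of the members' training seeds.
#' @return An object of class `ensemble_bundle`.
#' @export
ensemble_bundle <- function(members, seeds = vapply(members, function(m)
  m$seed, integer(1))) {
  if (length(members) < 1) stop("an ensemble needs at least one member")
  sp <- members[[1]]$spec
  for (m in members) {
    if (!identical(m$spec[c("widths", "strides", "pool_after", "input_px")],
                   sp[c("widths", "strides", "pool_after", "input_px")]))
      stop("all ensemble members must share one branch specification")
  }
  structure(list(members = members, seeds = as.integer(seeds)),
            class = "ensemble_bundle")
}

#' @export
print.ensemble_bundle <- function(x, ...) {
  cat(sprintf("<ensemble_bundle> M = %d members, seeds [%s]\n",
              length(x$members), paste(x$seeds, collapse = ", ")))
  print(x$members[[1]])
  invisible(x)
}

#' Fuse member scores into one grade distribution
#'
#' Core of the ensemble inference rule: the members' unnormalised
#' (pre-softmax) score vectors are summed and the sum is passed through a
#' numerically stabilised softmax. `fuse_logits()` is the pure arithmetic
#' on an M x 5 score matrix; `fuse()` runs the members on a patch pair
#' first. Adding a constant to any single member's scores shifts the sum
#' by a constant and therefore leaves the fused distribution unchanged.
#'
#' @param logits numeric M x 5 matrix of member scores (one row per member).
#' @return A [grade_distribution()].
#' @export
fuse_logits <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (ncol(logits) != 5) stop("member scores must have 5 columns")
  z <- colSums(logits)
  z <- z - max(z)
  e <- exp(z)
  grade_distribution(e / sum(e))
}

#' @rdname fuse_logits
#' @param bundle an [ensemble_bundle()].
#' @param pair a `patch_pair`.
#' @export
fuse <- function(bundle, pair) {
  stopifnot(inherits(bundle, "ensemble_bundle"))
  z <- t(vapply(bundle$members, function(m) siamese_logits(m, pair),
                numeric(5)))
  fuse_logits(z)
}

#' Predict grade distributions for many pairs
#'
#' Batched ensemble inference; pairs are processed in chunks to bound the
#' memory of the im2col buffers.
#'
#' @param bundle an [ensemble_bundle()].
#' @param pairs list of `patch_pair` objects.
#' @param chunk batch size per forward pass.
#' @return Numeric matrix with one row per pair and columns `KL0..KL4`.
#' @export
predict_pairs <- function(bundle, pairs, chunk = 32L) {
  n <- length(pairs)
  Z <- matrix(0, n, 5)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    zsum <- matrix(0, 5, length(idx))
    for (m in bundle$members)
      zsum <- zsum + siamese_forward(m, pairs[idx], training = FALSE)$logits
    zsum <- zsum - rep(apply(zsum, 2, max), each = 5)
    e <- exp(zsum)
    Z[idx, ] <- t(e) / colSums(e)
  }
  colnames(Z) <- paste0("KL", 0:4)
  Z
}

#' Radiographic-OA probability
#'
#' The binary radiographic osteoarthritis score: the probability mass on
#' grades KL >= 2, i.e. `probs[3] + probs[4] + probs[5]` in 1-based
#' indexing. This is the score used for the OA ROC curve.
#'
#' @param dist a [grade_distribution()] (or any length-5 probability
#'   vector / matrix with 5 columns).
#' @return Scalar (or vector) OA probability.
#' @export
oa_probability <- function(dist) {
  if (is.matrix(dist)) return(rowSums(dist[, 3:5, drop = FALSE]))
  sum(dist[3:5])
}
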