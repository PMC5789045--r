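#' Quadratic weighted Cohen's kappa
#'
#' Chance-corrected agreement between two graders on the ordinal KL scale
#' with quadratic weights `w_ij = 1 - (i - j)^2 / (K - 1)^2`: a one-grade
#' disagreement costs far less than an end-to-end one. Expected agreement
#' comes from the outer product of the two marginal distributions.
#'
#' @param truth,pred integer grade vectors (values in `0..(n_grades-1)`),
#'   equal length >= 2.
#' @param n_grades number of grades K (default 5).
#' @return Kappa in \[-1, 1\].
#' @export
quadratic_kappa <- function(truth, pred, n_grades = 5L) {
  if (length(truth) != length(pred)) stop("`truth` and `pred` lengths differ")
  if (length(truth) < 2) stop("kappa needs at least two ratings")
  K <- as.integer(n_grades)
  if (any(c(truth, pred) < 0) || any(c(truth, pred) > K - 1))
    stop("grades must lie in 0..", K - 1)
  O <- table(factor(truth, levels = 0:(K - 1)),
             factor(pred, levels = 0:(K - 1)))
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  D <- outer(0:(K - 1), 0:(K - 1), function(i, j) (i - j)^2) / (K - 1)^2
  denom <- sum(D * E)
  if (denom < .Machine$double.eps)
    stop("kappa is undefined: degenerate single-class marginals")
  1 - sum(D * O) / denom
}

#' Grade mean squared error
#'
#' MSE between the true grade and the hard (argmax) predicted grade —
#' the classification MSE used for ordinal comparison with other graders.
#'
#' @param truth integer grade vector.
#' @param pred_dist matrix of grade probabilities (rows = cases) or an
#'   integer vector of predicted grades.
#' @return Mean of squared grade differences.
#' @export
grade_mse <- function(truth, pred_dist) {
  pred <- if (is.matrix(pred_dist)) max.col(pred_dist, "first") - 1L
          else as.integer(pred_dist)
  if (length(truth) != length(pred)) stop("lengths differ")
  mean((as.numeric(truth) - pred)^2)
}

#' Average multi-class accuracy
#'
#' Mean per-class recall (balanced accuracy): the confusion-matrix diagonal
#' divided by row sums, averaged over classes that actually occur. Plain
#' accuracy is attached as an attribute since the two readings of
#' "average accuracy" differ under class imbalance.
#'
#' @param confusion square count matrix, rows = truth, cols = prediction.
#' @return Balanced accuracy in \[0, 1\], with attribute `plain`.
#' @export
avg_multiclass_accuracy <- function(confusion) {
  n <- sum(confusion)
  if (n <= 0) stop("empty confusion matrix")
  rs <- rowSums(confusion)
  keep <- rs > 0
  recall <- diag(as.matrix(confusion))[keep] / rs[keep]
  structure(mean(recall), plain = sum(diag(as.matrix(confusion))) / n)
}

#' Confusion matrix on the KL scale
#'
#' @param truth,pred integer grade vectors.
#' @param n_grades number of grades.
#' @return K x K count matrix, rows = truth, cols = prediction.
#' @export
confusion_matrix <- function(truth, pred, n_grades = 5L) {
  K <- as.integer(n_grades)
  unclass(table(truth = factor(truth, levels = 0:(K - 1)),
                pred = factor(pred, levels = 0:(K - 1))))
}

#' ROC curve and AUC for radiographic-OA diagnosis
#'
#' Binary ROC for the KL >= 2 diagnosis: truth is thresholded at grade 2
#' and the score is the predicted OA probability ([oa_probability()]).
#' The curve is swept over the unique score thresholds; the AUC is the
#' trapezoidal area, which with tied scores equals the rank-average
#' (Mann-Whitney) statistic.
#'
#' @param truth integer grade vector (or logical OA status).
#' @param scores numeric OA scores, higher = more diseased.
#' @return List with `curve` (data.frame of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
oa_roc <- function(truth, scores) {
  pos <- if (is.logical(truth)) truth else truth >= 2
  if (length(pos) != length(scores)) stop("lengths differ")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs both OA and non-OA cases")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)    # last index of each tied run
  tpr <- cumsum(p)[keep] / n_pos
  fpr <- cumsum(!p)[keep] / n_neg
  curve <- data.frame(threshold = c(Inf, s[keep]),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  prev_tpr <- c(0, tpr[-length(tpr)])
  auc <- sum(diff(c(0, fpr)) * (prev_tpr + tpr) / 2)
  list(curve = curve, auc = auc)
}

#' Weight-free architecture shape probe
#'
#' Reports the spatial side length of the last pre-pooling activation map
#' of an architecture by pure convolution arithmetic, without constructing
#' weights. `"siamese_branch"` traces the default five-convolution branch
#' (10 at 128 px input); `"resnet34"` traces the standard ResNet-34 stem
#' (7x7 stride-2 convolution, padding 3; 3x3 stride-2 max-pool, padding 1)
#' and its four residual stages of 3x3 convolutions (stages 2-4 downsample
#' by stride 2), giving 7 at 224 px input.
#'
#' @param arch `"siamese_branch"` or `"resnet34"`.
#' @param input_px square input size.
#' @param spec optional [branch_spec()] overriding the default branch.
#' @return Integer spatial side of the final activation map.
#' @export
shape_probe <- function(arch = c("siamese_branch", "resnet34"),
                        input_px = NULL, spec = NULL) {
  arch <- match.arg(arch)
  conv_out <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L
  if (arch == "siamese_branch") {
    if (is.null(input_px)) input_px <- 128L
    if (!is.null(spec)) {
      tr <- spatial_trace(input_px, spec$strides, spec$pool_after)
    } else {
      tr <- spatial_trace(input_px)
    }
    return(tr[length(tr)])
  }
  if (is.null(input_px)) input_px <- 224L
  n <- as.integer(input_px)
  n <- conv_out(n, 7L, 2L, 3L)     # stem convolution
  if (n < 1) stop("input too small for ResNet-34")
  n <- conv_out(n, 3L, 2L, 1L)     # stem max-pool
  for (stage_stride in c(1L, 2L, 2L, 2L)) {
    n <- conv_out(n, 3L, stage_stride, 1L)  # first conv of the stage
    if (n < 1) stop("input too small for ResNet-34")
    # remaining 3x3 convolutions are stride 1, padding 1: size-preserving
  }
  n
}

#' Full evaluation report
#'
#' The metric panel for a set of graded cases: confusion matrix, balanced
#' (and plain) multi-class accuracy, quadratic weighted kappa, grade MSE
#' and the radiographic-OA ROC/AUC.
#'
#' @param truth integer grade vector.
#' @param pred_dist matrix of grade probabilities, one row per case.
#' @return An object of class `kl_eval`.
#' @export
eval_report <- function(truth, pred_dist) {
  stopifnot(is.matrix(pred_dist), ncol(pred_dist) == 5,
            nrow(pred_dist) == length(truth))
  pred <- max.col(pred_dist, "first") - 1L
  conf <- confusion_matrix(truth, pred)
  acc <- avg_multiclass_accuracy(conf)
  roc <- tryCatch(oa_roc(truth, oa_probability(pred_dist)),
                  error = function(e) list(curve = NULL, auc = NA_real_))
  structure(list(confusion = conf,
                 avg_accuracy = as.numeric(acc),
                 plain_accuracy = attr(acc, "plain"),
                 kappa_quadratic = quadratic_kappa(truth, pred),
                 mse = grade_mse(truth, pred),
                 auc_oa = roc$auc, roc = roc$curve,
                 n = length(truth)),
            class = "kl_eval")
}

#' @export
print.kl_eval <- function(x, ...) {
  cat(sprintf("<kl_eval> n = %d knees\n", x$n))
  cat(sprintf("  balanced accuracy: %.4f (plain %.4f)\n",
              x$avg_accuracy, x$plain_accuracy))
  cat(sprintf("  quadratic kappa:   %.4f\n", x$kappa_quadratic))
  cat(sprintf("  grade MSE:         %.4f\n", x$mse))
  cat(sprintf("  OA (KL>=2) AUC:    %.4f\n", x$auc_oa))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
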