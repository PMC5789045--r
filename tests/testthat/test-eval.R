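test_that("quadratic kappa agrees with the brute-force contingency oracle", {
  expect_equal(quadratic_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), 1)

  # hand case against the explicit double-loop reference
  t0 <- c(0, 0, 4, 4)
  p0 <- c(0, 4, 0, 4)
  expect_equal(quadratic_kappa(t0, p0), kappa_reference(t0, p0),
               tolerance = 1e-14)

  set.seed(90)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    truth <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    if (length(unique(truth)) == 1 && length(unique(pred)) == 1) next
    expect_equal(quadratic_kappa(truth, pred),
                 kappa_reference(truth, pred), tolerance = 1e-12)
  }

  expect_error(quadratic_kappa(rep(2, 10), rep(2, 10)), "degenerate")
  expect_error(quadratic_kappa(0:3, 0:2), "lengths")
  expect_error(quadratic_kappa(1, 1), "at least two")
})

test_that("grade MSE uses hard argmax predictions", {
  P <- diag(5)[c(1, 2, 3, 4, 5), ]
  expect_equal(grade_mse(0:4, P), 0)
  expect_equal(grade_mse(0, matrix(c(0, 0, 0, 0, 1), 1)), 16)
  expect_equal(grade_mse(c(0, 1, 2, 3), c(1, 1, 2, 3)), 0.25)  # one off-by-one
  expect_equal(grade_mse(c(0, 0), c(1, 0)), 0.5)
})

test_that("balanced accuracy averages per-class recall over occupied rows", {
  expect_equal(as.numeric(avg_multiclass_accuracy(diag(5) * 10)), 1)

  conf <- confusion_matrix(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 0))
  # recalls: 1/2, 1, 0 over the three occupied rows
  expect_equal(as.numeric(avg_multiclass_accuracy(conf)), (0.5 + 1 + 0) / 3)
  expect_equal(attr(avg_multiclass_accuracy(conf), "plain"), 3 / 5)

  # uniform random predictions on balanced truth sit near chance
  set.seed(91)
  truth <- rep(0:4, each = 2000)
  pred <- sample(0:4, 10000, replace = TRUE)
  acc <- as.numeric(avg_multiclass_accuracy(confusion_matrix(truth, pred)))
  expect_lt(abs(acc - 0.2), 0.02)
})

test_that("ROC/AUC matches all-pairs Mann-Whitney and handles ties", {
  truth <- c(0, 1, 2, 3, 4, 0, 1, 3)
  scores <- c(0.1, 0.2, 0.9, 0.8, 0.95, 0.05, 0.15, 0.7)
  expect_equal(oa_roc(truth, scores)$auc, 1)   # perfectly separating

  set.seed(92)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    truth <- sample(0:4, n, replace = TRUE)
    if (all(truth >= 2) || all(truth < 2)) next
    scores <- round(runif(n), 1)               # coarse scores force ties
    r <- oa_roc(truth, scores)
    expect_equal(r$auc, auc_reference(scores[truth >= 2],
                                      scores[truth < 2]),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms of the scores
    expect_equal(oa_roc(truth, exp(3 * scores))$auc, r$auc)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }

  expect_error(oa_roc(rep(0, 5), runif(5)), "both")
})

test_that("AUC cross-checks against an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  truth <- sample(0:4, 150, replace = TRUE)
  scores <- runif(150) + 0.3 * (truth >= 2)
  ours <- oa_roc(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth >= 2, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("shape probes report the final activation side of both architectures", {
  expect_equal(shape_probe("siamese_branch", 128), 10L)
  expect_equal(shape_probe("resnet34", 224), 7L)
  # smaller branch input, recomputed by hand:
  # 64 ->31 ->29 ->pool 14 ->12 ->pool 6 ->4 ->2
  expect_equal(shape_probe("siamese_branch", 64), 2L)
  # resnet at 256: 256 ->128 ->64 ->64 ->32 ->16 ->8
  expect_equal(shape_probe("resnet34", 256), 8L)
  # padding keeps tiny inputs alive down to a 1x1 map
  expect_equal(shape_probe("resnet34", 32), 1L)
})

test_that("the evaluation report assembles a consistent metric panel", {
  set.seed(94)
  truth <- rep(0:4, each = 8)
  P <- matrix(runif(200), 40, 5)
  P <- P / rowSums(P)
  # tilt probabilities toward the truth
  P[cbind(seq_len(40), truth + 1)] <- P[cbind(seq_len(40), truth + 1)] + 1
  P <- P / rowSums(P)
  rep_ <- eval_report(truth, P)
  expect_s3_class(rep_, "kl_eval")
  expect_equal(sum(rep_$confusion), 40)
  expect_equal(rowSums(rep_$confusion),
               sapply(0:4, function(g) sum(truth == g)),
               ignore_attr = TRUE)
  expect_true(rep_$kappa_quadratic >= -1 && rep_$kappa_quadratic <= 1)
  expect_true(rep_$auc_oa >= 0 && rep_$auc_oa <= 1)
  pred <- max.col(P, "first") - 1L
  expect_equal(rep_$mse, mean((truth - pred)^2))
})
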