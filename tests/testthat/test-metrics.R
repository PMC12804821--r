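# Pixel metrics against brute-force oracles on small fixtures.

brute_confusion <- function(pred, truth, M = 5) {
  TP <- FP <- TN <- FN <- numeric(M)
  for (c in 0:(M - 1)) {
    for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == c; t <- truth[i, j] == c
      if (p && t) TP[c + 1] <- TP[c + 1] + 1
      else if (p && !t) FP[c + 1] <- FP[c + 1] + 1
      else if (!p && t) FN[c + 1] <- FN[c + 1] + 1
      else TN[c + 1] <- TN[c + 1] + 1
    }
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

test_that("confusion tallies match a brute-force double loop", {
  pred <- random_classes(8, 8, seed = 31)
  truth <- random_classes(8, 8, seed = 32)
  got <- confusion(pred, truth)
  ref <- brute_confusion(pred, truth)
  expect_equal(got$TP, ref$TP)
  expect_equal(got$FP, ref$FP)
  expect_equal(got$TN, ref$TN)
  expect_equal(got$FN, ref$FN)
  # tallies conserve the pixel total for every class
  expect_true(all(got$TP + got$FP + got$TN + got$FN == 64))
  # perfect prediction: no errors anywhere
  perf <- confusion(truth, truth)
  expect_true(all(perf$FP == 0) && all(perf$FN == 0))
  # forced single-pixel case
  one <- confusion(matrix(0L, 1, 1), matrix(3L, 1, 1))
  expect_equal(one$FP[1], 1)
  expect_equal(one$FN[4], 1)
  expect_equal(one$TN[2], 1)
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "mismatch")
})

test_that("rate metrics follow their defining ratios in all modes", {
  pred <- random_classes(8, 8, seed = 33)
  truth <- random_classes(8, 8, seed = 34)
  tl <- confusion(pred, truth)
  # micro accuracy == precision == recall for single-label pixels
  expect_equal(precision(tl, "micro"), recall(tl, "micro"), tolerance = 1e-12)
  acc_overall <- mean(pred == truth)
  expect_equal(recall(tl, "micro"), acc_overall, tolerance = 1e-12)
  # harmonic identity to 1e-12: F1 is the harmonic mean of its own P and R
  for (mode in c("micro", "per_class")) {
    p <- precision(tl, mode); r <- recall(tl, mode)
    f_ref <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
    expect_equal(unname(f1_score(tl, mode)), unname(f_ref), tolerance = 1e-12)
  }
  # macro F1 is the mean of the per-class harmonic means
  pc <- f1_score(tl, "per_class")
  expect_equal(f1_score(tl, "macro"), mean(pc), tolerance = 1e-12)
  # perfect prediction: everything 1
  perf <- confusion(truth, truth)
  for (mode in c("micro", "macro")) {
    expect_equal(pixel_accuracy(perf, mode), 1)
    expect_equal(f1_score(perf, mode), 1)
  }
  # zero-denominator handled as 0
  one <- confusion(matrix(0L, 1, 1), matrix(3L, 1, 1))
  expect_equal(unname(precision(one, "per_class")[1]), 0)
})

test_that("published headline precision/recall are harmonic-consistent", {
  # P = 97.14%, R = 96.90% combine to the printed F-score within rounding
  expect_equal(round(2 * 0.9714 * 0.9690 / (0.9714 + 0.9690), 4), 0.9702)
})

test_that("cross-entropy matches hand arithmetic and closed forms", {
  cls <- random_classes(4, 4, seed = 35)
  oh <- classes_to_onehot(cls)
  expect_equal(cce_loss(oh, oh), 0)
  unif <- array(0.2, c(4, 4, 5))
  expect_equal(cce_loss(unif, oh), log(5), tolerance = 1e-12)
  # 2-pixel fixture, hand-computed
  t2 <- classes_to_onehot(matrix(c(0L, 2L), 1, 2))
  p2 <- array(0, c(1, 2, 5))
  p2[1, 1, ] <- c(0.7, 0.1, 0.1, 0.05, 0.05)
  p2[1, 2, ] <- c(0.25, 0.25, 0.4, 0.05, 0.05)
  expect_equal(cce_loss(p2, t2), -(log(0.7) + log(0.4)) / 2, tolerance = 1e-12)
  expect_error(cce_loss(p2, classes_to_onehot(matrix(0L, 2, 2))), "mismatch")
})

test_that("mean IoU matches a brute-force set computation", {
  pred <- random_classes(4, 4, seed = 36)
  truth <- random_classes(4, 4, seed = 37)
  got <- mean_iou(pred, truth)
  ref <- vapply(0:4, function(c) {
    inter <- sum(pred == c & truth == c)
    uni <- sum(pred == c | truth == c)
    if (uni == 0) NA_real_ else inter / uni
  }, 0)
  expect_equal(unname(got$iou), ref)
  expect_equal(got$MIoU, mean(ref, na.rm = TRUE))
  expect_equal(mean_iou(truth, truth)$MIoU, 1)
  # disjoint class: IoU 0
  p <- matrix(0L, 2, 2); t <- matrix(1L, 2, 2)
  expect_equal(unname(mean_iou(p, t)$iou[1]), 0)
  # soil-free averaging mode
  expect_equal(mean_iou(pred, truth, include_classes = 0:3)$MIoU,
               mean(ref[1:4], na.rm = TRUE))
})

test_that("response-time measurement reports mean and variance", {
  m <- cauc_model("V2", 32, seed = 41)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  r1 <- mean_response_time(m, img, repeats = 1)
  expect_length(r1$times, 1)
  expect_equal(r1$MRT, r1$times[1])
  expect_gte(r1$MRT, 0)
  r3 <- mean_response_time(m, img, repeats = 3)
  expect_length(r3$times, 3)
  expect_gte(r3$var, 0)
  expect_error(mean_response_time(m, img, repeats = 0), ">= 1")
})

test_that("metrics_report aggregates the full scoreboard", {
  pred <- list(random_classes(6, 6, seed = 42), random_classes(6, 6, seed = 43))
  truth <- list(random_classes(6, 6, seed = 44), random_classes(6, 6, seed = 45))
  prob <- lapply(pred, function(p) classes_to_onehot(p) * 0.96 + 0.008)
  rep <- metrics_report(pred, truth, prob = prob, model = cauc_model("V2", 32))
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n_samples, 2L)
  rates <- c(rep$accuracy, rep$precision_micro, rep$recall_micro, rep$f1_micro,
             rep$precision_per_class, rep$recall_per_class, rep$MIoU)
  expect_true(all(rates >= 0 & rates <= 1))
  expect_gt(rep$loss, 0)
  expect_true(is.finite(rep$NPM) && rep$NPM > 0)
})
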