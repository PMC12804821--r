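# Pixel-wise evaluation metrics: one-vs-rest confusion tallies, accuracy /
# precision / recall / F1 in micro, macro and per-class modes, categorical
# cross-entropy, mean IoU, and response-time measurement.

#' One-vs-rest pixel confusion tallies
#'
#' @param pred predicted class rasters: an H x W integer matrix or a list of
#'   them (0-based classes).
#' @param truth ground-truth rasters of matching shape.
#' @param M class count (default 5).
#' @return a `confusion_tally`: list with per-class integer vectors `TP`,
#'   `FP`, `TN`, `FN`, plus `M` and `total` pixels.
#' @export
confusion <- function(pred, truth, M = 5L) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(truth)) truth <- list(truth)
  if (length(pred) != length(truth)) stop("pred and truth batch sizes differ")
  cm <- matrix(0, M, M) # rows = truth, cols = pred
  for (i in seq_along(pred)) {
    p <- pred[[i]]; t <- truth[[i]]
    if (!identical(dim(p), dim(t))) stop("pred/truth shape mismatch at sample ", i)
    if (any(p >= M) || any(t >= M) || any(p < 0) || any(t < 0)) {
      stop("class entries must lie in 0..", M - 1)
    }
    cm <- cm + table(factor(t, levels = 0:(M - 1)), factor(p, levels = 0:(M - 1)))
  }
  total <- sum(cm)
  TP <- diag(cm)
  FP <- colSums(cm) - TP
  FN <- rowSums(cm) - TP
  TN <- total - TP - FP - FN
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP), TN = as.numeric(TN),
                 FN = as.numeric(FN), M = M, total = total,
                 table = cm), class = "confusion_tally")
}

# rate with zero-denominator -> 0 (a warning record is attached upstream)
.safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

.tally_metric <- function(tally, mode, f) {
  mode <- match.arg(mode, c("micro", "per_class", "macro"))
  if (mode == "micro") {
    f(sum(tally$TP), sum(tally$FP), sum(tally$TN), sum(tally$FN))
  } else {
    v <- f(tally$TP, tally$FP, tally$TN, tally$FN)
    if (mode == "macro") mean(v) else stats::setNames(v, .CLASS_NAMES[seq_len(tally$M)])
  }
}

#' Pixel accuracy from a confusion tally
#'
#' Per class, the one-vs-rest form `(TP+TN)/(TP+FP+TN+FN)`. In micro mode
#' the overall fraction of correctly classified pixels (`sum(TP)/total`),
#' which for single-label pixel classification coincides with micro
#' precision and micro recall — the headline accuracy semantics.
#'
#' @param tally a [confusion()] result.
#' @param mode `"micro"` (fraction of pixels classified correctly),
#'   `"per_class"`, or `"macro"` (mean of per-class values).
#' @return numeric value(s) in [0, 1].
#' @export
pixel_accuracy <- function(tally, mode = "micro") {
  mode <- match.arg(mode, c("micro", "per_class", "macro"))
  if (mode == "micro") return(sum(tally$TP) / tally$total)
  .tally_metric(tally, mode, function(tp, fp, tn, fn) .safe_div(tp + tn, tp + fp + tn + fn))
}

#' Precision from a confusion tally
#'
#' @inheritParams pixel_accuracy
#' @return `TP/(TP+FP)` (0 where undefined).
#' @export
precision <- function(tally, mode = "micro") {
  .tally_metric(tally, mode, function(tp, fp, tn, fn) .safe_div(tp, tp + fp))
}

#' Recall from a confusion tally
#'
#' @inheritParams pixel_accuracy
#' @return `TP/(TP+FN)` (0 where undefined).
#' @export
recall <- function(tally, mode = "micro") {
  .tally_metric(tally, mode, function(tp, fp, tn, fn) .safe_div(tp, tp + fn))
}

#' F1 score from a confusion tally
#'
#' Harmonic mean of precision and recall: `2PR/(P+R)`.
#'
#' @inheritParams pixel_accuracy
#' @return numeric value(s) in [0, 1].
#' @export
f1_score <- function(tally, mode = "micro") {
  .tally_metric(tally, mode, function(tp, fp, tn, fn) {
    p <- .safe_div(tp, tp + fp)
    r <- .safe_div(tp, tp + fn)
    .safe_div(2 * p * r, p + r)
  })
}

#' Categorical cross-entropy loss
#'
#' Mean over pixels of `-sum_j A_ij log P_ij`, with probabilities clipped at
#' 1e-12. Reported per pixel so values are commensurable across image sizes.
#'
#' @param prob predicted probability volume(s): H x W x M array or list.
#' @param onehot matching one-hot target volume(s).
#' @return mean loss (nats per pixel).
#' @export
cce_loss <- function(prob, onehot) {
  if (is.array(prob) && length(dim(prob)) == 3) { prob <- list(prob); onehot <- list(onehot) }
  if (length(prob) != length(onehot)) stop("prob and onehot batch sizes differ")
  tot <- 0; npx <- 0
  for (i in seq_along(prob)) {
    p <- prob[[i]]; t <- onehot[[i]]
    if (!identical(dim(p), dim(t))) stop("prob/onehot shape mismatch at sample ", i)
    tot <- tot - sum(t * log(pmax(p, 1e-12)))
    npx <- npx + dim(p)[1] * dim(p)[2]
  }
  tot / npx
}

#' Mean intersection-over-union
#'
#' Per-class IoU pooled over all pixels of the batch, averaged over classes;
#' classes absent from both prediction and truth are excluded from the mean.
#'
#' @inheritParams confusion
#' @param include_classes optional 0-based class subset to average over
#'   (e.g. `0:3` to exclude soil).
#' @return list with `MIoU` and the per-class `iou` vector (NA where a class
#'   is absent from both).
#' @export
mean_iou <- function(pred, truth, M = 5L, include_classes = NULL) {
  tl <- confusion(pred, truth, M)
  union <- tl$TP + tl$FP + tl$FN
  iou <- ifelse(union == 0, NA_real_, tl$TP / union)
  names(iou) <- .CLASS_NAMES[seq_len(M)]
  keep <- if (is.null(include_classes)) seq_len(M) else include_classes + 1L
  vals <- iou[keep]
  if (all(is.na(vals))) stop("all classes absent from both prediction and truth")
  list(MIoU = mean(vals, na.rm = TRUE), iou = iou)
}

#' Mean response time of model inference
#'
#' Wall-clock seconds per image over repeated forward passes; reported with
#' its sample variance, never asserted against.
#'
#' @param model a `cauc_model`.
#' @param images list of input images (see [predict.cauc_model()]).
#' @param repeats number of timed passes over the batch.
#' @return list with `MRT` (seconds/image), `var` and the raw `times`.
#' @export
mean_response_time <- function(model, images, repeats = 1L) {
  if (repeats < 1) stop("repeats must be >= 1")
  if (is.array(images)) images <- list(images)
  times <- numeric(0)
  for (r in seq_len(repeats)) {
    for (im in images) {
      times <- c(times, system.time(predict(model, im))[["elapsed"]])
    }
  }
  list(MRT = mean(times), var = if (length(times) > 1) stats::var(times) else 0,
       times = times)
}

#' Full evaluation report for predictions against a labelled bundle
#'
#' @param model a `cauc_model` (used for NPM; optional).
#' @param pred list of predicted class rasters.
#' @param truth list of ground-truth class rasters.
#' @param prob optional list of probability volumes (enables the loss entry).
#' @param M class count.
#' @return a `metrics_report` list with micro and per-class A/P/R/FS, loss,
#'   MIoU (with and without soil), NPM and sizes.
#' @export
metrics_report <- function(pred, truth, prob = NULL, model = NULL, M = 5L) {
  tl <- confusion(pred, truth, M)
  mi <- mean_iou(pred, truth, M)
  mi_veg <- tryCatch(mean_iou(pred, truth, M, include_classes = 0:(M - 2L)),
                     error = function(e) list(MIoU = NA_real_))
  rep <- list(
    n_samples = if (is.matrix(pred)) 1L else length(pred),
    M = M,
    accuracy = pixel_accuracy(tl, "micro"),
    precision_micro = precision(tl, "micro"),
    recall_micro = recall(tl, "micro"),
    f1_micro = f1_score(tl, "micro"),
    precision_per_class = precision(tl, "per_class"),
    recall_per_class = recall(tl, "per_class"),
    f1_per_class = f1_score(tl, "per_class"),
    loss = if (!is.null(prob)) {
      oh <- lapply(if (is.matrix(truth)) list(truth) else truth, classes_to_onehot, M = M)
      cce_loss(prob, oh)
    } else NA_real_,
    MIoU = mi$MIoU,
    MIoU_without_soil = mi_veg$MIoU,
    iou_per_class = mi$iou,
    NPM = if (!is.null(model)) count_parameters(model) else NA_integer_
  )
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Pixel metrics over %d sample(s), %d classes\n", x$n_samples, x$M))
  cat(sprintf("  accuracy %.4f | P %.4f | R %.4f | F1 %.4f (micro)\n",
              x$accuracy, x$precision_micro, x$recall_micro, x$f1_micro))
  if (!is.na(x$loss)) cat(sprintf("  loss %.4f nats/pixel\n", x$loss))
  cat(sprintf("  MIoU %.4f (without soil %.4f)\n", x$MIoU, x$MIoU_without_soil))
  if (!is.na(x$NPM)) cat(sprintf("  NPM %s\n", format(x$NPM, big.mark = ",")))
  invisible(x)
}
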