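# Training: categorical cross-entropy, Adam, per-epoch logging, k-fold CV.
#
# The reference regime trains 224x224 inputs for 50 epochs with batch size 8
# at learning rate 0.001; any desk-scale reduction (smaller images, fewer
# samples) uses the same code path.

#' Training configuration
#'
#' @param epochs training epochs (default 50).
#' @param batch_size images per optimizer step (default 8).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param cv_folds folds for [run_cv()] (default 5).
#' @param seed master seed: weight init, shuffling and dropout derive from it.
#' @param variant model variant (default `"V5"`).
#' @param input_size square input side; masks and images must match.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, learning_rate = 0.001,
                         cv_folds = 5L, seed = 1L, variant = "V5",
                         input_size = 224L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, cv_folds >= 2)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), variant = variant,
                 input_size = as.integer(input_size)), class = "train_config")
}

#' Read a training configuration from a YAML file
#'
#' The file may set any subset of the [train_config()] fields (e.g.
#' `epochs: 50`, `batch_size: 8`, `learning_rate: 0.001`, `variant: V5`);
#' unset fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a `train_config`.
#' @export
read_train_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(train_config, vals)
}

.bundle_tensors <- function(bundle, input_size) {
  lapply(bundle$samples, function(s) {
    d <- dim(s$image)
    if (d[1] != input_size || d[2] != input_size) {
      stop(sprintf("sample %s is %dx%d but the model expects %dx%d",
                   s$sample_id, d[1], d[2], input_size, input_size))
    }
    cls <- mask_to_classes(s$mask, s$source_scheme)
    list(x = array(s$image / 255, d),
         t = .as_mat(classes_to_onehot(cls)),
         cls = cls)
  })
}

#' Train a segmentation model
#'
#' Minimizes per-pixel categorical cross-entropy with Adam. Fully
#' reproducible under the config seed (single-threaded deterministic mode).
#'
#' @param config a [train_config()].
#' @param train_bundle labelled `seg_bundle` for training.
#' @param val_bundle optional bundle evaluated after every epoch.
#' @param model optionally a pre-built `cauc_model` to continue training.
#' @param verbose print an epoch line.
#' @return a `cauc_fit`: list with `model`, `config` and `log` (one row per
#'   epoch: loss, pixel accuracy, optional validation metrics, wall time).
#' @export
cauc_train <- function(config, train_bundle, val_bundle = NULL, model = NULL,
                       verbose = FALSE) {
  if (!length(train_bundle$samples)) stop("training bundle is empty")
  if (is.null(model)) {
    model <- cauc_model(config$variant, config$input_size, seed = config$seed)
  }
  data <- .bundle_tensors(train_bundle, model$input_size)
  params <- .model_params(model)
  zero_grads(params)
  n <- length(data)
  log <- vector("list", config$epochs)
  step <- 0L
  .with_seed(.sub_seed(config$seed, 97L), {
    for (ep in seq_len(config$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0; ep_px <- 0
      for (b0 in seq(1L, n, config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        zero_grads(params)
        bl <- 0
        for (i in idx) {
          tp <- .tape()
          logits <- .forward_one(model, data[[i]]$x, training = TRUE, tape = tp)
          loss <- op_softmax_ce(tp, logits, data[[i]]$t)
          if (!is.finite(.v(loss))) stop("non-finite training loss at epoch ", ep)
          .backward(tp, loss)
          bl <- bl + .v(loss)
          pc <- prob_to_classes(softmax3(.v(logits)))
          ep_correct <- ep_correct + sum(pc == data[[i]]$cls)
          ep_px <- ep_px + length(pc)
        }
        step <- step + 1L
        adam_step(params, config$learning_rate, step, scale = 1 / length(idx))
        ep_loss <- ep_loss + bl
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n,
                        train_acc = ep_correct / ep_px,
                        val_loss = NA_real_, val_acc = NA_real_, val_f1 = NA_real_,
                        seconds = proc.time()[["elapsed"]] - t0)
      if (!is.null(val_bundle) && length(val_bundle$samples)) {
        vm <- evaluate(model, val_bundle, with_prob = TRUE)
        row$val_loss <- vm$loss; row$val_acc <- vm$accuracy; row$val_f1 <- vm$f1_micro
      }
      log[[ep]] <- row
      if (verbose) {
        message(sprintf("epoch %d/%d loss %.4f acc %.4f (%.1fs)", ep,
                        config$epochs, row$loss, row$train_acc, row$seconds))
      }
    }
  })
  structure(list(model = model, config = config, log = do.call(rbind, log)),
            class = "cauc_fit")
}

#' Evaluate a model on a labelled bundle
#'
#' @param model a `cauc_model` or `cauc_fit`.
#' @param bundle labelled `seg_bundle`.
#' @param with_prob also compute the cross-entropy loss (keeps probability
#'   volumes in memory).
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, bundle, with_prob = TRUE) {
  if (inherits(model, "cauc_fit")) model <- model$model
  if (!length(bundle$samples)) stop("evaluation bundle is empty")
  probs <- predict(model, bundle, type = "prob")
  pred <- lapply(probs, prob_to_classes)
  truth <- lapply(bundle$samples, function(s) mask_to_classes(s$mask, s$source_scheme))
  metrics_report(pred, truth, prob = if (with_prob) probs else NULL, model = model)
}

#' k-fold cross-validated training
#'
#' Stratified folds from [make_cv_folds()]; each fold trains on its ~80% and
#' is evaluated on the held-out ~20%.
#'
#' @param config a [train_config()] (its `cv_folds` sets k).
#' @param bundle labelled training bundle.
#' @param verbose print progress.
#' @return list with per-fold `reports`, the `fits`, and `summary`
#'   (mean and sd of headline metrics over folds).
#' @export
run_cv <- function(config, bundle, verbose = FALSE) {
  folds <- make_cv_folds(bundle, config$cv_folds, seed = .sub_seed(config$seed, 5L))
  reports <- vector("list", length(folds))
  fits <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    cfg <- config
    cfg$seed <- .sub_seed(config$seed, 200L + f)
    fit <- cauc_train(cfg, folds[[f]]$train, verbose = verbose)
    fits[[f]] <- fit
    reports[[f]] <- evaluate(fit, folds[[f]]$val)
  }
  pick <- function(field) vapply(reports, `[[`, 0, field)
  summary <- data.frame(
    metric = c("accuracy", "f1_micro", "MIoU", "loss"),
    mean = c(mean(pick("accuracy")), mean(pick("f1_micro")),
             mean(pick("MIoU")), mean(pick("loss"))),
    sd = c(stats::sd(pick("accuracy")), stats::sd(pick("f1_micro")),
           stats::sd(pick("MIoU")), stats::sd(pick("loss")))
  )
  list(reports = reports, fits = fits, summary = summary)
}

#' @export
print.cauc_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<cauc_fit %s: %d epochs, final loss %.4f, train acc %.4f>\n",
              x$model$variant, nrow(x$log), last$loss, last$train_acc))
  invisible(x)
}

#' @export
predict.cauc_fit <- function(object, images, ...) predict(object$model, images, ...)

#' Plot training curves of a fit
#'
#' @param x a `cauc_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cauc_fit <- function(x, ...) {
  lg <- x$log
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(lg$epoch, lg$loss, type = "l", xlab = "epoch", ylab = "loss", ...)
  if (!all(is.na(lg$val_loss))) graphics::lines(lg$epoch, lg$val_loss, lty = 2)
  graphics::plot(lg$epoch, lg$train_acc, type = "l", xlab = "epoch",
                 ylab = "pixel accuracy", ylim = c(0, 1), ...)
  if (!all(is.na(lg$val_acc))) graphics::lines(lg$epoch, lg$val_acc, lty = 2)
  invisible(x)
}
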