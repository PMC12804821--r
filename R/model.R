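# Assembly of the full segmentation network and its ablation variants.
#
# Trunk: conv stem (64 filters) -> four encoder LCBs (16/32/64/128 filters)
# each followed by 2x2 max-pool and channel dropout -> 256-filter DSC middle
# layer -> four decoder stages (upsample x2, channel dropout, attention-gated
# skip, concat, LCB at 128/64/32/16) -> CBAM feature fusion over all four
# decoder outputs upsampled to full resolution (240 channels) -> 3x3 output
# conv to the 5 class channels -> per-pixel softmax.
#
# Variants: V5 full model; V4 drops the fusion CBAMs (output from the last
# LCB's head); V3 replaces attention-gated skips with plain concatenation;
# V2 drops both; V1 is a typical U-Net (plain double-conv blocks at the
# classic 64/128/256/512 ladder, 1024 bottleneck, plain skips).

.ENC_N <- c(16L, 32L, 64L, 128L)
.ENC_DROP <- c(0.2, 0.2, 0.5, 0.5)
.DEC_N <- c(128L, 64L, 32L, 16L)
.DEC_DROP <- c(0.5, 0.5, 0.2, 0.2)
.VARIANTS <- c(V1 = "wo-CBAM_AG_LCB", V2 = "wo-CBAM_AG", V3 = "wo-AG",
               V4 = "wo-CBAM", V5 = "full")

#' Build the segmentation network (or an ablation variant)
#'
#' @param variant one of `"V1"` (plain U-Net: no LCB/AG/CBAM), `"V2"` (no
#'   AG, no CBAM), `"V3"` (no AG), `"V4"` (no CBAM), `"V5"` (full model).
#' @param input_size square input side in pixels; must be divisible by 16
#'   (the trunk downsamples four times).
#' @param num_classes output classes (default 5).
#' @param seed seed for weight initialization.
#' @return an object of class `cauc_model`.
#' @export
cauc_model <- function(variant = "V5", input_size = 224L, num_classes = 5L,
                       seed = 1L) {
  if (!variant %in% names(.VARIANTS)) {
    stop("unknown variant '", variant, "'; must be one of ",
         paste(names(.VARIANTS), collapse = ", "))
  }
  if (input_size %% 16 != 0) stop("input_size must be divisible by 16")
  input_size <- as.integer(input_size)
  if (variant == "V1") return(.build_unet(input_size, num_classes, seed))

  has_ag <- variant %in% c("V4", "V5")
  has_cbam <- variant %in% c("V3", "V5")
  .with_seed(seed, {
    stem <- new_conv_layer(3L, 3L, 64L)
    enc_ni <- c(64L, .ENC_N[1:3])
    enc <- lapply(1:4, function(i) lcb_block(.ENC_N[i], enc_ni[i]))
    mid <- dsc_block(128L, 256L)
    dec <- lapply(1:4, function(i) {
      m <- .DEC_N[i]
      list(
        ag = if (has_ag) ag_block(m, inter = m) else NULL,
        lcb = lcb_block(m, 2L * m + m) # concat of upsampled deeper (2m) + skip (m)
      )
    })
    cbams <- if (has_cbam) lapply(.DEC_N, cbam_block) else NULL
    op_cin <- if (has_cbam) sum(.DEC_N) else .DEC_N[4]
    opconv <- new_conv_layer(3L, op_cin, as.integer(num_classes),
                             bn = FALSE, act = "none", init_sd = 1e-4)
    structure(list(
      variant = variant, variant_name = .VARIANTS[[variant]],
      input_size = input_size, num_classes = as.integer(num_classes),
      seed = as.integer(seed), has_ag = has_ag, has_cbam = has_cbam,
      stem = stem, enc = enc, mid = mid, dec = dec, cbams = cbams,
      opconv = opconv, enc_drop = .ENC_DROP, dec_drop = .DEC_DROP,
      stages = .cauc_stage_table(input_size, num_classes, has_ag, has_cbam)
    ), class = "cauc_model")
  })
}

#' @rdname cauc_model
#' @export
build_cauc <- function(input_size = 224L, num_classes = 5L, seed = 1L) {
  cauc_model("V5", input_size, num_classes, seed)
}

# plain double-conv U-Net used as the V1 ablation reference
.build_unet <- function(input_size, num_classes, seed) {
  widths <- c(64L, 128L, 256L, 512L)
  bott <- 1024L
  dc <- function(cin, cout) list(new_conv_layer(3L, cin, cout),
                                 new_conv_layer(3L, cout, cout))
  .with_seed(seed, {
    enc <- lapply(1:4, function(i) dc(if (i == 1) 3L else widths[i - 1], widths[i]))
    mid <- dc(widths[4], bott)
    dec_w <- rev(widths)
    dec <- lapply(1:4, function(i) {
      deeper <- if (i == 1) bott else dec_w[i - 1]
      dc(deeper + dec_w[i], dec_w[i])
    })
    opconv <- new_conv_layer(1L, dec_w[4], as.integer(num_classes),
                             bn = FALSE, act = "none", init_sd = 1e-4)
    s <- input_size
    stages <- data.frame(
      stage = c(paste0("E", 1:4), "M", paste0("D", 1:4), "OP"),
      H = c(s, s / 2, s / 4, s / 8, s / 16, s / 8, s / 4, s / 2, s, s),
      W = c(s, s / 2, s / 4, s / 8, s / 16, s / 8, s / 4, s / 2, s, s),
      C = c(widths, bott, dec_w, num_classes)
    )
    structure(list(
      variant = "V1", variant_name = .VARIANTS[["V1"]],
      input_size = input_size, num_classes = as.integer(num_classes),
      seed = as.integer(seed), has_ag = FALSE, has_cbam = FALSE,
      enc = enc, mid = mid, dec = dec, opconv = opconv, stages = stages
    ), class = "cauc_model")
  })
}

# analytic stage/shape table mirroring the architecture configuration
.cauc_stage_table <- function(s, nc, has_ag, has_cbam) {
  r <- function(stage, f, c) data.frame(stage = stage, H = s / f, W = s / f, C = c)
  tb <- rbind(
    r("E1", 1, 64), r("E2", 1, 16), r("E3", 2, 16), r("E4", 2, 16),
    r("E5", 2, 32), r("E6", 4, 32), r("E7", 4, 32), r("E8", 4, 64),
    r("E9", 8, 64), r("E10", 8, 64), r("E11", 8, 128), r("E12", 16, 128),
    r("E13", 16, 128), r("M", 16, 256),
    r("D1", 8, 256), r("D2", 8, 256),
    if (has_ag) r("D3", 8, 128), r("D3c", 8, 384), r("D4", 8, 128),
    r("D5", 4, 128), r("D6", 4, 128),
    if (has_ag) r("D7", 4, 64), r("D8", 4, 192), r("D9", 4, 64),
    r("D10", 2, 64), r("D11", 2, 64),
    if (has_ag) r("D12", 2, 32), r("D13", 2, 96), r("D14", 2, 32),
    r("D15", 1, 32), r("D16", 1, 32),
    if (has_ag) r("D17", 1, 16), r("D18", 1, 48), r("D19", 1, 16)
  )
  if (has_cbam) {
    tb <- rbind(tb, r("F1", 1, 128), r("F2", 1, 64), r("F3", 1, 32),
                r("F4", 1, 16), r("F5", 1, 240))
  }
  tb <- rbind(tb, r("F6", 1, nc), r("F7", 1, nc))
  tb$H <- as.integer(tb$H); tb$W <- as.integer(tb$W); tb$C <- as.integer(tb$C)
  rownames(tb) <- NULL
  tb
}

#' Ordered stage/shape report of a built model
#'
#' @param model a `cauc_model`.
#' @return data.frame with columns `stage`, `H`, `W`, `C`, one row per
#'   architecture stage.
#' @export
shape_report <- function(model) {
  stopifnot(inherits(model, "cauc_model"))
  model$stages
}

#' Count trainable parameters of a model
#'
#' Sums per-layer parameter counts. With `include_bn = TRUE` (default) the
#' count matches a framework-style "total params" summary, including batch
#' normalization scale/shift and running statistics.
#'
#' @param model a `cauc_model`.
#' @param include_bn include batch-norm parameters.
#' @return integer count.
#' @export
count_parameters <- function(model, include_bn = TRUE) {
  stopifnot(inherits(model, "cauc_model"))
  weight_count(unclass(model)[setdiff(names(model), "stages")],
               include_bn = include_bn, include_bias = TRUE)
}

#' Census of convolution layers by kernel size
#'
#' Each depth-wise separable layer counts once under its spatial kernel size;
#' its pointwise half is part of the layer, not a separate 1x1 layer.
#'
#' @param model a `cauc_model`.
#' @return named integer vector, e.g. `c("1" = 32, "3" = 27, "7" = 4)`.
#' @export
layer_census <- function(model) {
  stopifnot(inherits(model, "cauc_model"))
  layers <- .collect_layers(unclass(model)[setdiff(names(model), "stages")])
  ks <- vapply(layers, function(l) l$K, 1L)
  tab <- table(ks)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# all trainable parameter environments of a model
.model_params <- function(model) {
  .collect_params(unclass(model)[setdiff(names(model), "stages")])
}

# ---- forward ---------------------------------------------------------------

# forward pass for one image (H x W x 3, values in [0,1]); returns the logits
# node (or array when tape is NULL)
.forward_one <- function(model, x, training = FALSE, tape = NULL) {
  d <- dim(.v(x))
  if (d[1] != model$input_size || d[2] != model$input_size || d[3] != 3L) {
    stop(sprintf("expected %dx%dx3 input, got %dx%dx%d",
                 model$input_size, model$input_size, d[1], d[2], d[3]))
  }
  tp <- tape
  if (model$variant == "V1") return(.forward_unet(model, x, training, tp))
  h <- .run_layer(model$stem, tp, x, training)
  skips <- vector("list", 4)
  for (i in 1:4) {
    s <- block_forward(model$enc[[i]], h, training = training, tape = tp)
    skips[[i]] <- s
    h <- op_maxpool2(tp, s)
    if (training && model$enc_drop[i] > 0) {
      h <- op_dropout(tp, h, model$enc_drop[i], channelwise = TRUE)
    }
  }
  deep <- block_forward(model$mid, h, training = training, tape = tp)
  dec_outs <- vector("list", 4)
  for (i in 1:4) {
    up <- op_upsample(tp, deep, 2L)
    if (training && model$dec_drop[i] > 0) {
      up <- op_dropout(tp, up, model$dec_drop[i], channelwise = TRUE)
    }
    skip <- skips[[5 - i]]
    gated <- if (model$has_ag) {
      block_forward(model$dec[[i]]$ag, skip, y = deep, training = training, tape = tp)
    } else skip
    deep <- block_forward(model$dec[[i]]$lcb, op_concat(tp, list(up, gated)),
                          training = training, tape = tp)
    dec_outs[[i]] <- deep
  }
  fused <- if (model$has_cbam) {
    op_concat(tp, lapply(1:4, function(i) {
      f <- block_forward(model$cbams[[i]], dec_outs[[i]],
                         training = training, tape = tp)
      sc <- 2L^(4L - i)
      if (sc > 1L) op_upsample(tp, f, sc) else f
    }))
  } else dec_outs[[4]]
  .run_layer(model$opconv, tp, fused, training)
}

.forward_unet <- function(model, x, training, tp) {
  run_dc <- function(blk, h) {
    h <- .run_layer(blk[[1]], tp, h, training)
    .run_layer(blk[[2]], tp, h, training)
  }
  skips <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    s <- run_dc(model$enc[[i]], h)
    skips[[i]] <- s
    h <- op_maxpool2(tp, s)
  }
  deep <- run_dc(model$mid, h)
  for (i in 1:4) {
    up <- op_upsample(tp, deep, 2L)
    deep <- run_dc(model$dec[[i]], op_concat(tp, list(up, skips[[5 - i]])))
  }
  .run_layer(model$opconv, tp, deep, training)
}

#' Forward pass: per-pixel class probabilities
#'
#' @param object a `cauc_model`.
#' @param images one H x W x 3 array (0..255 or already in [0,1]), a list of
#'   such arrays, or a `seg_bundle`.
#' @param type `"prob"` (H x W x M softmax volumes), `"class"` (H x W
#'   0-based class rasters) or `"mask"` (unified-palette masks).
#' @param ... unused.
#' @return a list with one element per image (a single array input returns
#'   the bare result).
#' @export
predict.cauc_model <- function(object, images, type = c("prob", "class", "mask"), ...) {
  type <- match.arg(type)
  single <- is.array(images)
  imgs <- if (inherits(images, "seg_bundle")) {
    lapply(images$samples, `[[`, "image")
  } else if (single) list(images) else images
  out <- lapply(imgs, function(im) {
    x <- if (max(im) > 1) im / 255 else im
    if (!is.double(x)) x <- array(as.double(x), dim(x))
    p <- softmax3(.forward_one(object, x, training = FALSE, tape = NULL))
    switch(type, prob = p, class = prob_to_classes(p), mask = prediction_to_mask(p))
  })
  if (single) out[[1]] else out
}

#' @export
print.cauc_model <- function(x, ...) {
  cat(sprintf("<cauc_model %s (%s): input %dx%dx3 -> %d classes, %s parameters>\n",
              x$variant, x$variant_name, x$input_size, x$input_size,
              x$num_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.cauc_model <- function(object, ...) {
  cen <- layer_census(object)
  cat(sprintf("Variant %s (%s), input %d, %d classes\n", object$variant,
              object$variant_name, object$input_size, object$num_classes))
  cat(sprintf("Parameters (incl. BN): %s; kernel weights only: %s\n",
              format(count_parameters(object), big.mark = ","),
              format(weight_count(unclass(object)[setdiff(names(object), "stages")],
                                  include_bn = FALSE, include_bias = FALSE),
                     big.mark = ",")))
  cat("Convolution layers by kernel size:\n")
  print(cen)
  cat("Stages:\n")
  print(utils::head(object$stages, 14))
  cat("  ... (", nrow(object$stages), " stages; see shape_report())\n", sep = "")
  invisible(object)
}

# ---- checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the serialized model plus a portable JSON architecture descriptor
#' alongside it.
#'
#' @param model a `cauc_model` (or `cauc_fit`).
#' @param path file path for the checkpoint (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  m <- if (inherits(model, "cauc_fit")) model$model else model
  desc <- list(
    variant = m$variant, input_size = m$input_size,
    num_classes = m$num_classes, seed = m$seed,
    parameters = count_parameters(m),
    stages = m$stages
  )
  jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return the restored object.
#' @export
load_checkpoint <- function(path) readRDS(path)
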