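# Hold-out splitting, augmentation-based resampling and k-fold CV.
#
# The split always precedes resampling, so no test sample is ever an
# augmented copy of a training sample (and vice versa). Geometric warps go
# through EBImage::affine: bilinear for images, nearest-neighbour for masks,
# so augmented masks never contain interpolated off-palette colours.

.AUG_OPS <- c("rotation", "zoom", "shear", "hflip", "vflip", "width_shift", "height_shift")

# default magnitude ranges (moderate, matching the visual effect of standard
# segmentation augmentation menus)
.AUG_RANGES <- list(
  rotation = c(-25, 25),        # degrees
  zoom = c(0.8, 1.2),           # scale factor
  shear = c(-10, 10),           # degrees
  width_shift = c(-0.1, 0.1),   # fraction of width
  height_shift = c(-0.1, 0.1)   # fraction of height
)

#' Augmentation specification
#'
#' @param op_name one of rotation, zoom, shear, hflip, vflip, width_shift,
#'   height_shift.
#' @param magnitude op-specific parameter (degrees, scale factor or shift
#'   fraction); ignored for flips. If `NULL`, a magnitude is drawn from the
#'   op's default range when the spec is applied.
#' @param seed seed used when `magnitude` is drawn.
#' @return an `aug_spec` object.
#' @export
aug_spec <- function(op_name, magnitude = NULL, seed = 0L) {
  if (!op_name %in% .AUG_OPS) {
    stop("unknown op_name '", op_name, "'; must be one of: ", paste(.AUG_OPS, collapse = ", "))
  }
  if (!is.null(magnitude) && op_name %in% names(.AUG_RANGES)) {
    r <- .AUG_RANGES[[op_name]]
    if (magnitude < r[1] || magnitude > r[2]) {
      stop(sprintf("magnitude %g outside configured range [%g, %g] for %s",
                   magnitude, r[1], r[2], op_name))
    }
  }
  structure(list(op_name = op_name, magnitude = magnitude, seed = as.integer(seed)),
            class = "aug_spec")
}

#' Draw a random augmentation spec from the default menu
#'
#' @param seed integer seed.
#' @return an `aug_spec`.
#' @export
random_aug_spec <- function(seed) {
  .with_seed(seed, {
    op <- sample(.AUG_OPS, 1)
    mag <- if (op %in% names(.AUG_RANGES)) {
      r <- .AUG_RANGES[[op]]
      runif(1, r[1], r[2])
    }
    aug_spec(op, mag, seed)
  })
}

# forward affine matrix (EBImage convention: [x' y'] = [x y 1] %*% m) for an
# op acting about the image centre; cx, cy in EBImage x/y coords
.affine_matrix <- function(op, mag, cx, cy) {
  A <- switch(op,
    rotation = {
      th <- mag * pi / 180
      matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    },
    zoom = diag(c(mag, mag)),
    shear = matrix(c(1, tan(mag * pi / 180), 0, 1), 2, 2),
    diag(2)
  )
  tr <- switch(op,
    width_shift = c(mag * 2 * cx, 0),
    height_shift = c(0, mag * 2 * cy),
    c(0, 0)
  )
  off <- c(cx, cy) - c(cx, cy) %*% t(A)
  rbind(t(A), as.numeric(off) + tr)
}

# warp one H x W plane; filter "bilinear" or "none" (nearest), constant fill
.warp_plane <- function(plane, m, filter, fill) {
  h <- nrow(plane); w <- ncol(plane)
  img <- EBImage::Image(t(plane))              # EBImage is x (col) major
  out <- EBImage::affine(img, m, filter = filter, bg.col = fill,
                         output.dim = c(w, h), antialias = FALSE)
  t(EBImage::imageData(out))
}

#' Apply one geometric augmentation identically to image and mask
#'
#' The image is interpolated bilinearly and regions warped in from outside
#' the frame are filled with a constant soil tone; the mask is warped with
#' nearest-neighbour sampling and soil-filled, so it remains palette-pure.
#'
#' @param sample a `seg_sample`.
#' @param spec an [aug_spec()].
#' @return a new `seg_sample` (sample_id gains an op suffix).
#' @export
augment_pair <- function(sample, spec) {
  stopifnot(inherits(sample, "seg_sample"), inherits(spec, "aug_spec"))
  op <- spec$op_name
  img <- sample$image
  msk <- sample$mask
  h <- dim(img)[1]; w <- dim(img)[2]

  if (op == "hflip") {
    img2 <- img[, w:1, , drop = FALSE]
    msk2 <- msk[, w:1, , drop = FALSE]
  } else if (op == "vflip") {
    img2 <- img[h:1, , , drop = FALSE]
    msk2 <- msk[h:1, , , drop = FALSE]
  } else {
    mag <- spec$magnitude
    if (is.null(mag)) {
      r <- .AUG_RANGES[[op]]
      mag <- .with_seed(spec$seed, runif(1, r[1], r[2]))
    }
    if ((op == "rotation" || op == "shear") && abs(mag) < 1e-12) {
      img2 <- img; msk2 <- msk
    } else if (op == "zoom" && abs(mag - 1) < 1e-12) {
      img2 <- img; msk2 <- msk
    } else {
      m <- .affine_matrix(op, mag, (w + 1) / 2, (h + 1) / 2)
      soil_img <- c(124, 92, 60) / 255   # constant soil tone fill
      soil_msk <- .UNIFIED_COLORS["soil", ] / 255
      img2 <- array(0L, dim(img)); msk2 <- array(0L, dim(msk))
      for (ch in 1:3) {
        p <- .warp_plane(img[, , ch] / 255, m, "bilinear", soil_img[ch])
        img2[, , ch] <- as.integer(pmin(255, pmax(0, round(p * 255))))
        q <- .warp_plane(msk[, , ch] / 255, m, "none", soil_msk[ch])
        msk2[, , ch] <- as.integer(round(q * 255))
      }
    }
  }
  structure(list(
    image = img2, mask = msk2, crop_id = sample$crop_id,
    source_scheme = sample$source_scheme,
    sample_id = paste0(sample$sample_id, "+", op, spec$seed)
  ), class = "seg_sample")
}

#' 90:10 hold-out split, stratified by crop
#'
#' Each crop's samples are split independently by random sub-sampling;
#' the per-crop training size is `round(train_ratio * n)`, so the source
#' datasets of 60, 1800 and 146 pairs split 54/6, 1620/180 and 131/15.
#'
#' @param bundle a `seg_bundle`.
#' @param train_ratio fraction in (0,1), default 0.9.
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `seg_bundle`s.
#' @export
holdout_split <- function(bundle, train_ratio = 0.9, seed = 1L) {
  if (!length(bundle$samples)) stop("cannot split an empty bundle")
  stopifnot(train_ratio > 0, train_ratio < 1)
  crops <- vapply(bundle$samples, `[[`, "", "crop_id")
  tr_idx <- integer(0)
  .with_seed(seed, {
    for (crop in unique(crops)) {
      idx <- which(crops == crop)
      n_tr <- round(train_ratio * length(idx))
      tr_idx <- c(tr_idx, sort(sample(idx, n_tr)))
    }
  })
  te_idx <- setdiff(seq_along(bundle$samples), tr_idx)
  list(
    train = new_bundle(bundle$samples[sort(tr_idx)], "train"),
    test = new_bundle(bundle$samples[te_idx], "test")
  )
}

#' Resampling plan
#'
#' @param target_train training images per crop after resampling (default 1000).
#' @param target_test test images per crop after resampling (default 100).
#' @param direction `"auto"` (upsample or downsample as needed per crop),
#'   `"upsample"`, `"downsample"`, or `"none"`.
#' @return a `resample_plan`.
#' @export
resample_plan <- function(target_train = 1000L, target_test = 100L,
                          direction = c("auto", "upsample", "downsample", "none")) {
  direction <- match.arg(direction)
  stopifnot(target_train >= 0, target_test >= 0)
  structure(list(target_train = as.integer(target_train),
                 target_test = as.integer(target_test),
                 direction = direction), class = "resample_plan")
}

#' Resample a split bundle to balanced per-crop counts
#'
#' Under-sized crops are upsampled by adding augmented copies (originals
#' retained, each copy a randomly chosen source pair under a randomly drawn
#' op from the default menu); over-sized crops are reduced by uniform random
#' sub-sampling without replacement.
#'
#' @param bundle a `seg_bundle` with split_tag `"train"` or `"test"` (the tag
#'   selects which plan target applies).
#' @param plan a [resample_plan()].
#' @param seed integer seed.
#' @return a `seg_bundle` with exactly the target count per crop.
#' @export
resample_to_target <- function(bundle, plan = resample_plan(), seed = 1L) {
  if (plan$direction == "none") return(bundle)
  target <- if (identical(bundle$split_tag, "test")) plan$target_test else plan$target_train
  crops <- vapply(bundle$samples, `[[`, "", "crop_id")
  out <- list()
  for (crop in unique(crops)) {
    idx <- which(crops == crop)
    n <- length(idx)
    if (n > target) {
      if (plan$direction == "upsample") {
        stop(sprintf("crop %s has %d > target %d but direction is 'upsample'", crop, n, target))
      }
      keep <- .with_seed(.sub_seed(seed, match(crop, .CLASS_NAMES)),
                         sort(sample(idx, target)))
      out <- c(out, bundle$samples[keep])
    } else if (n < target) {
      if (plan$direction == "downsample") {
        stop(sprintf("crop %s has %d < target %d but direction is 'downsample'", crop, n, target))
      }
      out <- c(out, bundle$samples[idx])
      need <- target - n
      for (i in seq_len(need)) {
        cs <- .sub_seed(seed, 1000L * match(crop, .CLASS_NAMES) + i)
        src <- bundle$samples[[idx[(i - 1L) %% n + 1L]]]
        aug <- augment_pair(src, random_aug_spec(cs))
        aug$sample_id <- sprintf("%s_aug%04d", src$sample_id, i)
        out <- c(out, list(aug))
      }
    } else {
      out <- c(out, bundle$samples[idx])
    }
  }
  new_bundle(out, bundle$split_tag)
}

#' Split, then resample, a raw dataset bundle
#'
#' Convenience wrapper: 90:10 hold-out split stratified by crop, then
#' resampling of both splits to the plan's targets.
#'
#' @inheritParams holdout_split
#' @param plan a [resample_plan()].
#' @return list with resampled `train` and `test` bundles.
#' @export
prepare_dataset <- function(bundle, plan = resample_plan(), train_ratio = 0.9, seed = 1L) {
  sp <- holdout_split(bundle, train_ratio, seed)
  list(
    train = resample_to_target(sp$train, plan, .sub_seed(seed, 11L)),
    test = resample_to_target(sp$test, plan, .sub_seed(seed, 13L))
  )
}

#' Stratified k-fold cross-validation folds
#'
#' Validation parts are pairwise disjoint, their union is the whole bundle,
#' and each fold is stratified by crop.
#'
#' @param bundle a `seg_bundle`.
#' @param k number of folds (default 5, i.e. an 8:2 train/validation split).
#' @param seed integer seed.
#' @return list of k elements, each `list(train = , val = )` of `seg_bundle`s.
#' @export
make_cv_folds <- function(bundle, k = 5L, seed = 1L) {
  n <- length(bundle$samples)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds bundle size (", n, ")")
  crops <- vapply(bundle$samples, `[[`, "", "crop_id")
  fold_of <- integer(n)
  .with_seed(seed, {
    off <- 0L # rotate the fold cycle across crops so fold sizes balance
    for (crop in unique(crops)) {
      idx <- sample(which(crops == crop))
      fold_of[idx] <- ((off + seq_along(idx) - 1L) %% k) + 1L
      off <- off + length(idx)
    }
  })
  if (any(tabulate(fold_of, k) == 0L)) stop("k (", k, ") leaves an empty fold")
  lapply(seq_len(k), function(f) {
    list(
      train = new_bundle(bundle$samples[fold_of != f], paste0("fold-", f, "-train")),
      val = new_bundle(bundle$samples[fold_of == f], paste0("fold-", f, "-val"))
    )
  })
}
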