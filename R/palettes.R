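# Label palettes and mask <-> class conversions.
#
# Three source annotation schemes plus the unified palette used for training.
# Class map (fixed): carrot=0, sugar_beet=1, sunflower=2, weed=3, soil=4.

.CLASS_NAMES <- c("carrot", "sugar_beet", "sunflower", "weed", "soil")
.N_CLASSES <- 5L

# unified palette: pure primaries; soil is black
.UNIFIED_COLORS <- rbind(
  carrot     = c(0L, 0L, 255L),
  sugar_beet = c(0L, 255L, 0L),
  sunflower  = c(0L, 255L, 255L),
  weed       = c(255L, 0L, 0L),
  soil       = c(0L, 0L, 0L)
)

#' Label palette for a mask annotation scheme
#'
#' Returns the colour table of one of the supported annotation schemes. The
#' three source datasets annotate crops and weeds with conflicting colours
#' (the carrot dataset marks crops red and weeds green; the sugar-beet and
#' sunflower datasets mark crops green and weeds red), so masks are recoloured
#' into a single unified palette before training: carrot blue, sugar beet
#' green, sunflower turquoise, weed red, soil black.
#'
#' @param scheme one of `"cwfid"`, `"sugar_beet"`, `"sunflower"`, `"unified"`.
#' @return an object of class `label_palette`: a list with `scheme`, a matrix
#'   `colors` (one row per class present in the scheme, columns R,G,B in
#'   0..255) and an integer vector `class_index` giving each row's class in
#'   the fixed 5-class map (0-based).
#' @export
label_palette <- function(scheme = c("unified", "cwfid", "sugar_beet", "sunflower")) {
  scheme <- match.arg(scheme)
  pal <- switch(scheme,
    unified = list(colors = .UNIFIED_COLORS, class_index = 0:4),
    cwfid = list(
      colors = rbind(crop = c(255L, 0L, 0L), weed = c(0L, 255L, 0L), soil = c(0L, 0L, 0L)),
      class_index = c(0L, 3L, 4L) # crop here is carrot
    ),
    sugar_beet = list(
      colors = rbind(crop = c(0L, 255L, 0L), weed = c(255L, 0L, 0L), soil = c(0L, 0L, 0L)),
      class_index = c(1L, 3L, 4L)
    ),
    sunflower = list(
      colors = rbind(crop = c(0L, 255L, 0L), weed = c(255L, 0L, 0L), soil = c(0L, 0L, 0L)),
      class_index = c(2L, 3L, 4L)
    )
  )
  structure(c(list(scheme = scheme), pal), class = "label_palette")
}

#' @export
print.label_palette <- function(x, ...) {
  cat("<label_palette '", x$scheme, "'>\n", sep = "")
  df <- data.frame(
    role = rownames(x$colors), R = x$colors[, 1], G = x$colors[, 2],
    B = x$colors[, 3], class = x$class_index, row.names = NULL
  )
  print(df)
  invisible(x)
}

# Match every pixel of an H x W x 3 integer mask to a palette row.
# Pixels within Euclidean RGB distance <= snap of a palette colour snap to it;
# anything further is an error naming the colour and a coordinate.
.match_palette <- function(mask, pal, snap = 30) {
  stopifnot(length(dim(mask)) == 3, dim(mask)[3] == 3)
  h <- dim(mask)[1]; w <- dim(mask)[2]
  px <- matrix(as.numeric(mask), h * w, 3)
  d2 <- vapply(seq_len(nrow(pal$colors)), function(i) {
    colSums((t(px) - pal$colors[i, ])^2)
  }, numeric(h * w))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = h * w)
  idx <- max.col(-d2, ties.method = "first")
  best <- d2[cbind(seq_len(h * w), idx)]
  bad <- which(best > snap^2)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "mask pixel at (row %d, col %d) has colour (%d,%d,%d) not within %g of any '%s' palette colour",
      (b - 1) %% h + 1, (b - 1) %/% h + 1,
      mask[(b - 1) %% h + 1, (b - 1) %/% h + 1, 1],
      mask[(b - 1) %% h + 1, (b - 1) %/% h + 1, 2],
      mask[(b - 1) %% h + 1, (b - 1) %/% h + 1, 3],
      snap, pal$scheme
    ))
  }
  matrix(idx, h, w)
}

#' Recolour a source-scheme mask into the unified palette
#'
#' Pixel colours are matched against the source palette (with a snap tolerance
#' of 30 RGB units to absorb compression artifacts) and redrawn in the unified
#' palette, preserving the semantic class of every pixel.
#'
#' @param mask H x W x 3 integer array (0..255).
#' @param source_scheme annotation scheme of `mask`.
#' @param snap maximum Euclidean RGB distance for colour snapping.
#' @return H x W x 3 integer array in the unified palette.
#' @export
recolor_mask <- function(mask, source_scheme, snap = 30) {
  pal <- label_palette(source_scheme)
  row <- .match_palette(mask, pal, snap)
  cls <- matrix(pal$class_index[row], nrow(row), ncol(row))
  classes_to_mask(cls)
}

#' Convert a palette mask to an integer class raster
#'
#' @param mask H x W x 3 integer array.
#' @param palette a `label_palette` or scheme name (default unified).
#' @param snap snap tolerance in RGB units.
#' @return H x W integer matrix with entries in 0..4
#'   (carrot, sugar_beet, sunflower, weed, soil).
#' @export
mask_to_classes <- function(mask, palette = "unified", snap = 30) {
  if (!inherits(palette, "label_palette")) palette <- label_palette(palette)
  row <- .match_palette(mask, palette, snap)
  matrix(palette$class_index[row], nrow(row), ncol(row))
}

#' Convert a class raster back to a unified-palette mask
#'
#' @param classes H x W integer matrix with entries in 0..4.
#' @return H x W x 3 integer array in the unified palette.
#' @export
classes_to_mask <- function(classes) {
  if (any(classes < 0L | classes >= .N_CLASSES)) {
    stop("class raster entries must lie in 0..", .N_CLASSES - 1L)
  }
  h <- nrow(classes); w <- ncol(classes)
  out <- array(0L, c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- matrix(.UNIFIED_COLORS[classes + 1L, ch], h, w)
  out
}

#' One-hot encode a class raster
#'
#' @param classes H x W integer matrix, entries in 0..M-1.
#' @param M class count (default 5).
#' @return H x W x M array of 0/1 with exactly one 1 per pixel.
#' @export
classes_to_onehot <- function(classes, M = .N_CLASSES) {
  if (any(classes < 0L | classes >= M)) stop("class raster entries must lie in 0..", M - 1L)
  h <- nrow(classes); w <- ncol(classes)
  out <- array(0, c(h, w, M))
  idx <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h), as.integer(classes) + 1L)
  out[idx] <- 1
  out
}

#' Decode a probability volume to a unified-palette mask
#'
#' Takes the per-pixel argmax over the class channels (ties broken toward the
#' lowest class index) and paints it in the unified palette.
#'
#' @param prob H x W x 5 array of finite per-class scores.
#' @return H x W x 3 integer mask.
#' @export
prediction_to_mask <- function(prob) {
  if (length(dim(prob)) != 3 || dim(prob)[3] != .N_CLASSES) {
    stop("probability volume must have ", .N_CLASSES, " channels")
  }
  if (!all(is.finite(prob))) stop("probability volume contains non-finite values")
  classes_to_mask(prob_to_classes(prob))
}

#' Per-pixel argmax of a probability volume
#'
#' @param prob H x W x M array.
#' @return H x W integer matrix of 0-based class indices.
#' @export
prob_to_classes <- function(prob) {
  h <- dim(prob)[1]; w <- dim(prob)[2]; m <- dim(prob)[3]
  flat <- matrix(prob, h * w, m)
  matrix(max.col(flat, ties.method = "first") - 1L, h, w)
}
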