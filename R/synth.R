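# Synthetic crop-field image/mask generator.
#
# Emulates the statistical structure of the field datasets the segmentation
# model is trained on: soil-dominated scenes (~94% of pixels), one crop
# species per image plus scattered weeds, perfect ground-truth masks in the
# unified palette. Species are separable by canopy shape and hue: carrot as
# thin feathery lobe clusters, sugar beet as broad paired ellipses, sunflower
# as large round blobs with radial lobes, weeds as small irregular blobs.

#' Configuration for the synthetic field generator
#'
#' @param image_size pixels per side (square images); must be >= 32.
#' @param soil_fraction_target expected fraction of soil pixels, in (0,1).
#'   Blob areas are budgeted so vegetation consumes roughly
#'   `1 - soil_fraction_target` of the image.
#' @param crops_per_image integer range (length 2) of crop plants per image.
#' @param weeds_per_image integer range of weed blobs per image.
#' @param noise_level additive pixel noise standard deviation (0..255 scale).
#' @param boundary_jitter logical; if TRUE the vegetation outlines are
#'   perturbed by per-lobe angular noise (annotation remains exact: the mask
#'   always matches the rendered vegetation).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_size = 224L, soil_fraction_target = 0.94,
                         crops_per_image = c(2L, 4L), weeds_per_image = c(2L, 5L),
                         noise_level = 8, boundary_jitter = FALSE) {
  stopifnot(image_size >= 32, soil_fraction_target > 0, soil_fraction_target < 1,
            length(crops_per_image) == 2, length(weeds_per_image) == 2,
            noise_level >= 0)
  structure(list(
    image_size = as.integer(image_size),
    soil_fraction_target = soil_fraction_target,
    crops_per_image = as.integer(crops_per_image),
    weeds_per_image = as.integer(weeds_per_image),
    noise_level = noise_level,
    boundary_jitter = isTRUE(boundary_jitter)
  ), class = "synth_config")
}

# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic per-item sub-seed, kept well below 2^31
.sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483587)
}

# elliptical blob membership on the pixel grid; optional angular radius
# modulation gives lobed / irregular outlines
.blob <- function(h, w, cx, cy, a, b, theta = 0, lobes = 0, lobe_depth = 0, phase = 0) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), w), h, w) - cy
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  r2 <- (xr / a)^2 + (yr / b)^2
  if (lobes > 0) {
    ang <- atan2(yr / b, xr / a)
    mod <- 1 + lobe_depth * cos(lobes * ang + phase)
    r2 <- r2 / pmax(mod, 0.15)^2
  }
  r2 <= 1
}

# one plant footprint of a given species and target area (pixels)
.plant_mask <- function(species, h, w, cx, cy, area, jitter = FALSE) {
  m <- matrix(FALSE, h, w)
  jd <- if (jitter) 0.25 else 0
  if (species == "carrot") {
    # feathery cluster: several thin rotated ellipses radiating from centre
    k <- sample(4:6, 1)
    la <- area / k
    for (i in seq_len(k)) {
      th <- runif(1, 0, pi)
      b <- sqrt(la / pi / 4.5)      # thin: aspect 4.5
      a <- 4.5 * b
      off <- a * 0.45
      m <- m | .blob(h, w, cx + off * cos(th), cy + off * sin(th), a, b, th,
                     lobes = if (jitter) 7 else 0, lobe_depth = jd)
    }
  } else if (species == "sugar_beet") {
    # broad paired leaves
    th <- runif(1, 0, pi)
    b <- sqrt(area / 2 / pi / 1.8)
    a <- 1.8 * b
    off <- a * 0.75
    m <- .blob(h, w, cx + off * cos(th), cy + off * sin(th), a, b, th, lobes = if (jitter) 5 else 0, lobe_depth = jd) |
      .blob(h, w, cx - off * cos(th), cy - off * sin(th), a, b, th, lobes = if (jitter) 5 else 0, lobe_depth = jd)
  } else if (species == "sunflower") {
    # large round blob with radial lobes
    r <- sqrt(area / pi)
    m <- .blob(h, w, cx, cy, r, r, 0, lobes = sample(6:9, 1),
               lobe_depth = 0.28 + jd, phase = runif(1, 0, 2 * pi))
  } else { # weed
    th <- runif(1, 0, pi)
    b <- sqrt(area / pi / 1.6)
    a <- 1.6 * b
    m <- .blob(h, w, cx, cy, a, b, th, lobes = sample(3:5, 1),
               lobe_depth = 0.35 + jd, phase = runif(1, 0, 2 * pi))
  }
  m
}

# smooth brown soil texture: coarse noise upsampled + fine noise
.soil_texture <- function(h, w, noise_level) {
  base <- c(124, 92, 60)
  ch <- max(4L, h %/% 8L); cw <- max(4L, w %/% 8L)
  coarse <- matrix(rnorm(ch * cw, 0, 14), ch, cw)
  up <- coarse[rep(seq_len(ch), length.out = h, each = ceiling(h / ch))[seq_len(h)],
               rep(seq_len(cw), length.out = w, each = ceiling(w / cw))[seq_len(w)]]
  # light box smoothing of the upsampled field
  sm <- (up +
    up[c(1, seq_len(h - 1)), ] + up[c(seq_len(h - 1) + 1, h), ] +
    up[, c(1, seq_len(w - 1))] + up[, c(seq_len(w - 1) + 1, w)]) / 5
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- base[k] + sm * c(1, 0.8, 0.6)[k] + rnorm(h * w, 0, noise_level)
  img
}

# vegetation hues per class (green-hued, species-separable)
.veg_color <- function(class_name) {
  switch(class_name,
    carrot     = c(55, 130, 45),
    sugar_beet = c(40, 160, 60),
    sunflower  = c(95, 165, 40),
    weed       = c(70, 145, 95)
  )
}

#' Generate one synthetic field image with its ground-truth mask
#'
#' Draws a soil-textured scene containing plants of a single crop species plus
#' scattered weeds, and the exact unified-palette label mask. Output is
#' deterministic in `(config, crop_id, seed)`.
#'
#' @param config a [synth_config()].
#' @param crop_id one of `"carrot"`, `"sugar_beet"`, `"sunflower"`.
#' @param seed integer seed.
#' @param sample_id optional id string; defaults to `"<crop>_<seed>"`.
#' @return an object of class `seg_sample`: list with `image` (H x W x 3
#'   integer, 0..255), `mask` (H x W x 3 integer, unified palette), `crop_id`,
#'   `source_scheme = "unified"`, `sample_id`.
#' @export
generate_field_sample <- function(config = synth_config(), crop_id, seed,
                                  sample_id = NULL) {
  crops <- .CLASS_NAMES[1:3]
  if (!crop_id %in% crops) {
    stop("unknown crop_id '", crop_id, "'; must be one of: ", paste(crops, collapse = ", "))
  }
  s <- config$image_size
  .with_seed(seed, {
    veg_budget <- (1 - config$soil_fraction_target) * s^2
    n_crop <- sample(seq(config$crops_per_image[1], config$crops_per_image[2]), 1)
    n_weed <- if (config$weeds_per_image[2] >= 1) {
      sample(seq(max(1L, config$weeds_per_image[1]), config$weeds_per_image[2]), 1)
    } else 0L
    crop_area <- 0.75 * veg_budget / n_crop
    weed_area <- if (n_weed > 0) 0.25 * veg_budget / n_weed else 0

    cls <- matrix(4L, s, s) # soil everywhere
    # crop plants roughly on a row with jitter
    row_y <- runif(1, 0.3, 0.7) * s
    xs <- (seq_len(n_crop) - 0.5) / n_crop * s + runif(n_crop, -0.06 * s, 0.06 * s)
    ys <- row_y + runif(n_crop, -0.12 * s, 0.12 * s)
    ci <- match(crop_id, .CLASS_NAMES) - 1L
    for (i in seq_len(n_crop)) {
      m <- .plant_mask(crop_id, s, s, xs[i], ys[i], crop_area, config$boundary_jitter)
      cls[m] <- ci
    }
    # weeds scattered away from the crop row
    for (i in seq_len(n_weed)) {
      wy <- runif(1, 0.05, 0.95) * s
      if (abs(wy - row_y) < 0.15 * s) wy <- ((wy + 0.3 * s - 1) %% s) + 1
      wx <- runif(1, 0.05, 0.95) * s
      m <- .plant_mask("weed", s, s, wx, wy, weed_area, config$boundary_jitter)
      cls[m] <- 3L
    }

    img <- .soil_texture(s, s, config$noise_level)
    for (k in unique(as.vector(cls))) {
      if (k == 4L) next
      col <- .veg_color(.CLASS_NAMES[k + 1L])
      sel <- cls == k
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- col[ch] + rnorm(sum(sel), 0, config$noise_level)
        img[, , ch] <- plane
      }
    }
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), c(s, s, 3))
    structure(list(
      image = img,
      mask = classes_to_mask(cls),
      crop_id = crop_id,
      source_scheme = "unified",
      sample_id = if (is.null(sample_id)) paste0(crop_id, "_", seed) else sample_id
    ), class = "seg_sample")
  })
}

#' @export
print.seg_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<seg_sample %s: %dx%d %s, soil %.1f%%>\n", x$sample_id, d[1], d[2],
              x$crop_id, 100 * soil_fraction(x)))
  invisible(x)
}

#' Generate a bundle of synthetic samples with given per-crop counts
#'
#' @param config a [synth_config()].
#' @param counts named integer vector, e.g.
#'   `c(carrot = 60, sugar_beet = 1800, sunflower = 146)`.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param split_tag label stored on the bundle (default `"all"`).
#' @return an object of class `seg_bundle`: list with `samples` (list of
#'   `seg_sample`), `split_tag` and `counts`.
#' @export
generate_dataset <- function(config = synth_config(), counts, seed, split_tag = "all") {
  if (is.null(names(counts)) || !all(names(counts) %in% .CLASS_NAMES[1:3])) {
    stop("counts must be named with crop ids: ", paste(.CLASS_NAMES[1:3], collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  samples <- list()
  j <- 0L
  for (crop in names(counts)) {
    for (i in seq_len(counts[[crop]])) {
      j <- j + 1L
      samples[[j]] <- generate_field_sample(
        config, crop, .sub_seed(seed, j),
        sample_id = sprintf("%s_%05d", crop, i)
      )
    }
  }
  new_bundle(samples, split_tag)
}

#' Construct a sample bundle
#'
#' @param samples list of `seg_sample` objects (sample_ids must be unique).
#' @param split_tag split label.
#' @return a `seg_bundle`.
#' @export
new_bundle <- function(samples, split_tag = "all") {
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("sample_ids must be unique")
  crops <- vapply(samples, `[[`, "", "crop_id")
  structure(list(
    samples = samples,
    split_tag = split_tag,
    counts = if (length(crops)) table(crops) else table(character())
  ), class = "seg_bundle")
}

#' @export
print.seg_bundle <- function(x, ...) {
  cat(sprintf("<seg_bundle '%s': %d samples>\n", x$split_tag, length(x$samples)))
  if (length(x$samples)) print(x$counts)
  invisible(x)
}

#' @export
length.seg_bundle <- function(x) length(x$samples)

#' Fraction of soil pixels in a sample's mask
#'
#' Counts mask pixels equal to the soil palette colour; any pixel outside the
#' palette raises an error naming the offending colour.
#'
#' @param sample a `seg_sample` (or a bare H x W x 3 mask array).
#' @return fraction in [0, 1].
#' @export
soil_fraction <- function(sample) {
  mask <- if (inherits(sample, "seg_sample")) sample$mask else sample
  scheme <- if (inherits(sample, "seg_sample")) sample$source_scheme else "unified"
  cls <- mask_to_classes(mask, scheme, snap = 0)
  mean(cls == 4L)
}

#' Write a bundle to disk as PNG images + manifest
#'
#' Writes `images/<id>.png`, `masks/<id>.png` and a `manifest.json` recording
#' sample_id, crop_id, split_tag and palette scheme.
#'
#' @param bundle a `seg_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- lapply(bundle$samples, function(s) {
    png::writePNG(s$image / 255, file.path(dir, "images", paste0(s$sample_id, ".png")))
    png::writePNG(s$mask / 255, file.path(dir, "masks", paste0(s$sample_id, ".png")))
    list(sample_id = s$sample_id, crop_id = s$crop_id,
         split_tag = bundle$split_tag, scheme = s$source_scheme)
  })
  jsonlite::write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing `images/`, `masks/`, `manifest.json`.
#' @return a `seg_bundle`.
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  samples <- lapply(man, function(m) {
    img <- png::readPNG(file.path(dir, "images", paste0(m$sample_id, ".png")))
    msk <- png::readPNG(file.path(dir, "masks", paste0(m$sample_id, ".png")))
    structure(list(
      image = array(as.integer(round(img * 255)), dim(img)),
      mask = array(as.integer(round(msk * 255)), dim(msk)),
      crop_id = m$crop_id, source_scheme = m$scheme, sample_id = m$sample_id
    ), class = "seg_sample")
  })
  new_bundle(samples, man[[1]]$split_tag %||% "all")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
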