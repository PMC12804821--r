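# Synthetic field generator: determinism, palette closure, class structure,
# soil dominance.

test_that("generation is deterministic and seed-sensitive", {
  cfg <- tiny_config()
  a <- generate_field_sample(cfg, "carrot", seed = 1)
  b <- generate_field_sample(cfg, "carrot", seed = 1)
  expect_identical(a, b)
  c2 <- generate_field_sample(cfg, "carrot", seed = 2)
  expect_false(identical(a$image, c2$image))
  # same structure: dims and palette
  expect_identical(dim(a$image), dim(c2$image))
  expect_palette_pure(c2$mask)
})

test_that("masks contain only the generating crop, weeds and soil", {
  cfg <- tiny_config()
  for (crop in c("carrot", "sugar_beet", "sunflower")) {
    s <- generate_field_sample(cfg, crop, seed = 7)
    cls <- unique(as.vector(mask_to_classes(s$mask, snap = 0)))
    crop_idx <- match(crop, c("carrot", "sugar_beet", "sunflower")) - 1L
    expect_true(all(cls %in% c(crop_idx, 3L, 4L)))
    # class presence: at least one crop and one weed pixel
    expect_true(crop_idx %in% cls)
    expect_true(3L %in% cls)
    expect_true(4L %in% cls)
  }
  expect_error(generate_field_sample(cfg, "maize", seed = 1), "carrot")
})

test_that("plant pixels are green-hued and soil pixels brown-hued", {
  s <- generate_field_sample(tiny_config(64), "sugar_beet", seed = 3)
  cls <- mask_to_classes(s$mask)
  r <- s$image[, , 1]; g <- s$image[, , 2]; b <- s$image[, , 3]
  veg <- cls != 4L
  expect_gt(mean(g[veg] > r[veg]), 0.95)   # vegetation: green dominates red
  expect_gt(mean(r[!veg] > b[!veg]), 0.95) # soil: red channel above blue
})

test_that("soil fraction tracks its target", {
  cfg <- synth_config() # defaults: 224 px, target 0.94
  fr <- vapply(1:100, function(i) {
    soil_fraction(generate_field_sample(cfg, c("carrot", "sugar_beet", "sunflower")[i %% 3 + 1],
                                        seed = i))
  }, 0)
  expect_gte(mean(fr), 0.90)
  expect_lte(mean(fr), 0.97)
  # single default sample close to the configured target
  expect_lt(abs(fr[1] - cfg$soil_fraction_target), 0.05)
})

test_that("soil_fraction is an exact pixel count", {
  all_soil <- classes_to_mask(matrix(4L, 10, 10))
  expect_equal(soil_fraction(all_soil), 1.0)
  one_weed <- matrix(4L, 224, 224)
  one_weed[100, 100] <- 3L
  expect_equal(soil_fraction(classes_to_mask(one_weed)), 1 - 1 / 50176)
  bad <- classes_to_mask(matrix(4L, 4, 4))
  bad[2, 2, ] <- c(7L, 7L, 7L)
  expect_error(soil_fraction(bad), "colour")
})

test_that("generate_dataset honours counts, uniqueness and determinism", {
  cfg <- tiny_config()
  b <- generate_dataset(cfg, c(carrot = 3, sugar_beet = 2, sunflower = 1), seed = 5)
  expect_equal(length(b), 6L)
  expect_equal(as.integer(b$counts[c("carrot", "sugar_beet", "sunflower")]), c(3L, 2L, 1L))
  ids <- vapply(b$samples, `[[`, "", "sample_id")
  expect_equal(anyDuplicated(ids), 0L)
  b2 <- generate_dataset(cfg, c(carrot = 3, sugar_beet = 2, sunflower = 1), seed = 5)
  expect_identical(b, b2)
  expect_equal(length(generate_dataset(cfg, c(carrot = 0), seed = 1)), 0L)
  expect_error(generate_dataset(cfg, c(carrot = -1), seed = 1), ">= 0")
})

test_that("bundles round-trip through PNG + manifest on disk", {
  b <- tiny_bundle(n = 3)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  b2 <- read_bundle(dir)
  expect_equal(length(b2), 3L)
  expect_identical(b2$samples[[2]]$image, b$samples[[2]]$image)
  expect_identical(b2$samples[[2]]$mask, b$samples[[2]]$mask)
  expect_identical(b2$samples[[2]]$crop_id, b$samples[[2]]$crop_id)
})
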