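# Shared fixtures: everything is generated in code at test time.

tiny_config <- function(size = 32) synth_config(image_size = size)

# small labelled bundle with all three crop species present
tiny_bundle <- function(n = 6, size = 32, seed = 100) {
  crops <- rep(c("carrot", "sugar_beet", "sunflower"), length.out = n)
  samples <- lapply(seq_len(n), function(i) {
    generate_field_sample(tiny_config(size), crops[i], seed = seed + i,
                          sample_id = sprintf("s%03d", i))
  })
  new_bundle(samples, "train")
}

# random class raster
random_classes <- function(h, w, M = 5, seed = 1) {
  set.seed(seed)
  matrix(sample(0:(M - 1), h * w, replace = TRUE), h, w)
}

expect_palette_pure <- function(mask) {
  expect_silent(mask_to_classes(mask, snap = 0))
}
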