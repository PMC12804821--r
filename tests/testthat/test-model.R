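# Model assembly: stage shapes, parameter totals, layer census, variants,
# forward contract.

test_that("stage shapes match the packaged architecture expectation table", {
  m <- cauc_model("V5", 224)
  fixture <- utils::read.csv(system.file("extdata", "cauc_stage_shapes.csv",
                                         package = "caucseg"))
  got <- shape_report(m)
  expect_equal(got$stage, fixture$stage)
  expect_equal(got$H, fixture$H)
  expect_equal(got$W, fixture$W)
  expect_equal(got$C, fixture$C)
  # spot checks on load-bearing stages
  expect_equal(unlist(got[got$stage == "M", c("H", "W", "C")], use.names = FALSE),
               c(14L, 14L, 256L))
  expect_equal(got$C[got$stage == "D8"], 192L)
  expect_equal(got$C[got$stage == "E3"], 16L)
  expect_equal(got$C[got$stage == "F5"], 240L)
  expect_equal(unlist(got[got$stage == "F7", c("H", "W", "C")], use.names = FALSE),
               c(224L, 224L, 5L))
})

test_that("parameter total sits at the design budget and the census is exact", {
  m <- cauc_model("V5", 224)
  npm <- count_parameters(m)
  expect_gt(npm, 0.377e6 * 0.95)
  expect_lt(npm, 0.377e6 * 1.05)
  cen <- layer_census(m)
  expect_equal(unname(cen["3"]), 27L) # stem + 24 LCB DSC + middle + output head
  expect_equal(unname(cen["7"]), 4L)  # one per fusion CBAM
  expect_equal(unname(cen["1"]), 32L) # 2 per LCB + 4 per attention gate
  # kernel-only count for a single DSC follows the factorized form
  expect_equal(weight_count(dsc_block(64, 128, seed = 1),
                            include_bn = FALSE, include_bias = FALSE), 8768)
})

test_that("ablation variants scale parameters in the documented order", {
  n5 <- count_parameters(cauc_model("V5", 224))
  n4 <- count_parameters(cauc_model("V4", 224))
  n3 <- count_parameters(cauc_model("V3", 224))
  n2 <- count_parameters(cauc_model("V2", 224))
  n1 <- count_parameters(cauc_model("V1", 224))
  expect_gt(n1, 10 * n5)
  expect_gt(n5, n4)
  expect_gt(n4, n2)
  expect_gt(n3, n2)
  # no CBAM -> no 7x7 convolutions
  expect_false("7" %in% names(layer_census(cauc_model("V1", 224))))
  expect_false("7" %in% names(layer_census(cauc_model("V4", 224))))
  expect_error(cauc_model("V9"), "unknown variant")
  expect_error(cauc_model("V5", 100), "divisible by 16")
})

test_that("forward produces normalized per-pixel distributions, deterministically", {
  m <- cauc_model("V5", 32, seed = 21)
  set.seed(22)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  p1 <- predict(m, img)
  expect_equal(dim(p1), c(32L, 32L, 5L))
  sums <- apply(p1, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  p2 <- predict(m, img)
  expect_identical(p1, p2) # inference is deterministic
  # batch of several images; class/mask decodings agree
  imgs <- lapply(1:8, function(i) array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)))
  ps <- predict(m, imgs)
  expect_length(ps, 8)
  cls <- predict(m, imgs[[1]], type = "class")
  expect_identical(cls, prob_to_classes(ps[[1]]))
  expect_identical(predict(m, imgs[[1]], type = "mask"), classes_to_mask(cls))
  expect_error(predict(m, array(0, c(16, 16, 3))), "expected 32x32x3")
})

test_that("variant forwards keep the output contract", {
  set.seed(23)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (v in c("V2", "V3", "V4")) {
    p <- predict(cauc_model(v, 32, seed = 24), img)
    expect_equal(dim(p), c(32L, 32L, 5L))
    expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
  }
})

test_that("checkpoints round-trip with identical predictions", {
  m <- cauc_model("V5", 32, seed = 25)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  desc <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(desc$parameters, count_parameters(m))
  m2 <- load_checkpoint(path)
  set.seed(26)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict(m, img), predict(m2, img))
})
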