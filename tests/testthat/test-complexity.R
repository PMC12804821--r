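# Parameter-reduction calculus and its brute-force counting oracle.

test_that("layer count formulas are exact products and sums", {
  expect_equal(np_sc(3, 64, 128), 73728)
  expect_equal(np_sc(1, 1, 1), 1)
  expect_equal(np_sc(3, 3, 64), 1728)     # stem on RGB
  expect_equal(np_dsc(3, 64, 128), 8768)
  expect_equal(np_dsc(3, 128, 256), 33920) # middle layer
  expect_equal(np_dsc(1, 1, 1), 2)
  expect_error(np_sc(0, 1, 1), "positive")
  expect_error(np_dsc(3, -2, 4), "positive")
})

test_that("per-layer DSC reduction behaves as the closed form prescribes", {
  expect_equal(pr1(16), 1 / 9 + 1 / 16)
  expect_equal(round(100 * pr1(16)), 17)
  expect_equal(floor(100 * pr1(256) + 0.5), 12) # round half up
  # strictly decreasing in N, approaching 1/9
  ns <- 2^(4:10)
  expect_true(all(diff(pr1(ns)) < 0))
  expect_equal(pr1(1e9), 1 / 9, tolerance = 1e-8)
  # np ratio identity: pr1 = np_dsc / np_sc
  expect_equal(pr1(128), np_dsc(3, 64, 128) / np_sc(3, 64, 128))
})

test_that("model-wide DSC average lands at the design figure", {
  filters <- cauc_dsc_filters()
  expect_length(filters, 25)                    # 24 LCB layers + middle
  expect_equal(sum(filters == 256), 1)
  expect_equal(round(100 * apr1(filters)), 14)
  expect_equal(apr1(64), pr1(64))               # single layer
  expect_equal(apr1(rep(32, 7)), pr1(32))       # constant list
  expect_error(apr1(numeric(0)), "nonempty")
})

test_that("side-specialized forms match their algebra and limits", {
  expect_equal(pr2_side("encoder", 64), 1 / 3 + 128 / (3 * 137))
  expect_equal(pr2_side("decoder", 64), 1 / 3 + 64 / (4 * 73))
  expect_equal(pr2_side("encoder", 1e-9), 1 / 3, tolerance = 1e-6)
  expect_equal(pr2_side("decoder", 1e-9), 1 / 3, tolerance = 1e-6)
  # pr2 under the side conventions reduces to the side forms
  x <- c(16, 32, 64, 128)
  expect_equal(pr2(2 * x, x), pr2_side("encoder", x), tolerance = 1e-12)
  expect_equal(pr2(x, 2 * x), pr2_side("decoder", x), tolerance = 1e-12)
  expect_error(pr2_side("middle", 4), "arg")
})

test_that("pooled 1x1 reduction average lands at the design figure", {
  a <- apr2(c(16, 32, 64, 128), c(16, 32, 64, 128))
  expect_equal(round(100 * a$APR2), 58)
  expect_gte(a$APR2, min(a$APR2E, a$APR2D))
  expect_lte(a$APR2, max(a$APR2E, a$APR2D))
  one <- apr2(32, 32)
  expect_equal(one$APR2, (one$APR2E + one$APR2D) / 2)
  expect_error(apr2(numeric(0), 16), "nonempty")
})

test_that("closed-form pr2 equals brute-force counting on a grid of blocks", {
  for (N in c(16, 32, 48, 64, 96, 128)) {
    for (Ni in c(8, 16, 32, 64, 128, 256)) {
      expect_equal(pr2(N, Ni), empirical_pr2(N, Ni), tolerance = 1e-12)
      expect_lt(pr2(N, Ni), 1)
      expect_gt(pr2(N, Ni), 0)
    }
  }
  # ratio decreases as Ni grows with N fixed
  vals <- vapply(c(8, 16, 32, 64, 128, 256), function(ni) empirical_pr2(64, ni), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("the complexity report carries consistent totals", {
  rep <- complexity_report(cauc_model("V5", 224))
  expect_equal(rep$m, 25L)
  expect_equal(rep$NE, 4L)
  expect_equal(rep$ND, 4L)
  expect_true(all(unlist(rep[c("pr1_per_layer", "APR1", "APR2E", "APR2D", "APR2")]) > 0))
  expect_true(all(unlist(rep[c("pr1_per_layer", "APR1", "APR2E", "APR2D", "APR2")]) < 1))
  expect_gt(rep$NPM, rep$kernel_weights) # biases + BN on top of kernels
  # empirical ratios for the actual graph agree with pr2 at the actual Ni
  expect_equal(unname(rep$empirical_pr2_encoder),
               pr2(c(16, 32, 64, 128), c(64, 16, 32, 64)), tolerance = 1e-12)
})
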