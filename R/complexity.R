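# Parameter-reduction calculus for the depth-wise separable and 1x1
# bottleneck design, with a brute-force counting oracle over real block
# instantiations.
#
# All formula-side counts enumerate convolution kernel weights only (no
# biases, no normalization parameters), and the empirical counterparts use
# the same exclusion.

#' Kernel-weight count of a standard convolution layer
#'
#' @param K kernel size.
#' @param IC input channels.
#' @param NF filters.
#' @return `K^2 * IC * NF`.
#' @export
np_sc <- function(K, IC, NF) {
  .check_pos(K, IC, NF)
  K * K * IC * NF
}

#' Kernel-weight count of a depth-wise separable convolution layer
#'
#' @param K kernel size.
#' @param IC input channels.
#' @param N filters.
#' @return `K^2 * IC + IC * N`.
#' @export
np_dsc <- function(K, IC, N) {
  .check_pos(K, IC, N)
  K * K * IC + IC * N
}

.check_pos <- function(...) {
  v <- c(...)
  if (any(v < 1)) stop("arguments must be positive integers")
}

#' Per-layer parameter-reduction ratio of depth-wise separable convolution
#'
#' The ratio of kernel weights in a depth-wise separable layer to those of
#' the standard convolution it replaces; for kernel size 3 this is
#' `1/9 + 1/N`, falling from ~17% at N = 16 to ~12% at N = 256.
#'
#' @param N filter count.
#' @param K kernel size (default 3).
#' @return ratio in (0, 1).
#' @export
pr1 <- function(N, K = 3) {
  if (any(N < 1)) stop("N must be >= 1")
  1 / K^2 + 1 / N
}

#' Average parameter-reduction ratio over a set of DSC layers
#'
#' @param filters vector of filter counts, one per depth-wise separable
#'   layer (the full model has 25: three per LCB at 16/32/64/128 on each
#'   side, plus the 256-filter middle layer).
#' @param K kernel size.
#' @return mean of [pr1()] over the layers.
#' @export
apr1 <- function(filters, K = 3) {
  if (!length(filters)) stop("filter list must be nonempty")
  mean(pr1(filters, K))
}

#' DSC layer filter allocation of the full model
#'
#' Three DSC layers per LCB at filter allocations 16/32/64/128 on the
#' encoder and decoder sides, plus the 256-filter middle layer (m = 25).
#'
#' @return integer vector of length 25.
#' @export
cauc_dsc_filters <- function() {
  c(rep(rep(.ENC_N, each = 3L), 2L), 256L)
}

#' Per-LCB parameter-reduction ratio from the 1x1 bottleneck layers
#'
#' Ratio of kernel weights in an LCB with its two 1x1 bottlenecks to the
#' same block without them (where each DSC consumes the accumulated
#' concatenation directly): `(3 + N/2 + N^2/(4(N+Ni))) / (9+N)`.
#'
#' @param N filter allocation of the block.
#' @param Ni input channel count.
#' @param K kernel size (fixed at 3 in the closed form).
#' @return ratio in (0, 1).
#' @export
pr2 <- function(N, Ni, K = 3) {
  if (any(N < 1) || any(Ni < 1)) stop("N and Ni must be >= 1")
  (K^2 / 3 + N / 2 + N^2 / (4 * (N + Ni))) / (K^2 + N)
}

#' Side-specialized 1x1 reduction ratios
#'
#' On the encoder side the filter allocation doubles the input (`Ni = x`,
#' `N = 2x`) giving `1/3 + 2x/(3(9+2x))`; on the decoder side it halves
#' (`Ni = 2x`, `N = x`) giving `1/3 + x/(4(9+x))`.
#'
#' @param side `"encoder"` or `"decoder"`.
#' @param x the side's base filter count.
#' @return ratio in (0, 1).
#' @export
pr2_side <- function(side = c("encoder", "decoder"), x) {
  side <- match.arg(side)
  if (any(x <= 0)) stop("x must be positive")
  if (side == "encoder") 1 / 3 + 2 * x / (3 * (9 + 2 * x))
  else 1 / 3 + x / (4 * (9 + x))
}

#' Pooled average 1x1 parameter-reduction ratio
#'
#' @param encoder_xs base filter counts of the encoder LCBs.
#' @param decoder_xs base filter counts of the decoder LCBs.
#' @return list with `APR2E`, `APR2D` (side means) and `APR2` (pooled mean
#'   over all NE + ND blocks).
#' @export
apr2 <- function(encoder_xs = .ENC_N, decoder_xs = .ENC_N) {
  if (!length(encoder_xs) || !length(decoder_xs)) stop("both side lists must be nonempty")
  pe <- pr2_side("encoder", encoder_xs)
  pd <- pr2_side("decoder", decoder_xs)
  list(APR2E = mean(pe), APR2D = mean(pd),
       APR2 = (sum(pe) + sum(pd)) / (length(pe) + length(pd)))
}

#' Empirical 1x1 reduction ratio by brute-force weight counting
#'
#' Builds the LCB with and without its two 1x1 bottleneck layers (the
#' "without" variant feeds each concatenation straight into the next DSC, so
#' channels accumulate: DSC(Ni->N), DSC(Ni+N->N), DSC(Ni+2N->N)), counts
#' convolution kernel weights only in both, and returns the ratio.
#'
#' @param N filter allocation.
#' @param Ni input channel count.
#' @return ratio in (0, 1).
#' @export
empirical_pr2 <- function(N, Ni) {
  with_1x1 <- lcb_block(N, Ni, seed = 1L)
  without <- list(
    new_dsc_layer(Ni, N),
    new_dsc_layer(Ni + N, N),
    new_dsc_layer(Ni + 2L * N, N)
  )
  num <- weight_count(with_1x1, include_bn = FALSE, include_bias = FALSE)
  den <- weight_count(without, include_bn = FALSE, include_bias = FALSE)
  num / den
}

#' Full complexity report for a built model
#'
#' Collects the per-layer and per-block reduction ratios (formula side),
#' their empirical counterparts from brute-force weight counting, and the
#' model's parameter totals. Carries both the idealized pattern reading
#' (`Ni = x`/`2x` as the side forms assume) and the actual graph-derived
#' input channels (the first encoder LCB really receives the 64-channel stem
#' output).
#'
#' @param model a `cauc_model` (default: the full V5 model structure).
#' @return a `complexity_report` list.
#' @export
complexity_report <- function(model = cauc_model("V5")) {
  filters <- cauc_dsc_filters()
  enc_ni_actual <- c(64L, .ENC_N[1:3])
  dec_ni_actual <- 3L * .DEC_N
  a2 <- apr2(.ENC_N, .ENC_N)
  rep <- list(
    m = length(filters),
    NE = 4L, ND = 4L,
    pr1_per_layer = stats::setNames(pr1(filters), filters),
    APR1 = apr1(filters),
    pr2_encoder_ideal = pr2(2L * .ENC_N, .ENC_N),
    pr2_decoder_ideal = pr2(.DEC_N, 2L * .DEC_N),
    pr2_encoder_actual = pr2(.ENC_N, enc_ni_actual),
    pr2_decoder_actual = pr2(.DEC_N, dec_ni_actual),
    APR2E = a2$APR2E, APR2D = a2$APR2D, APR2 = a2$APR2,
    empirical_pr2_encoder = mapply(empirical_pr2, .ENC_N, enc_ni_actual),
    empirical_pr2_decoder = mapply(empirical_pr2, .DEC_N, dec_ni_actual),
    NPM = count_parameters(model),
    kernel_weights = weight_count(
      unclass(model)[setdiff(names(model), "stages")],
      include_bn = FALSE, include_bias = FALSE
    )
  )
  structure(rep, class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Parameter-reduction report\n")
  cat(sprintf("  APR1 over %d DSC layers: %.1f%%\n", x$m, 100 * x$APR1))
  cat(sprintf("  APR2: %.1f%% (encoder %.1f%%, decoder %.1f%%)\n",
              100 * x$APR2, 100 * x$APR2E, 100 * x$APR2D))
  cat(sprintf("  NPM: %s (kernel weights only: %s)\n",
              format(x$NPM, big.mark = ","),
              format(x$kernel_weights, big.mark = ",")))
  invisible(x)
}
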