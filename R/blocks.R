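# Building blocks: depth-wise separable convolution (DSC), the Linear
# Concatenated Block (LCB), the attention gate (AG) on skip connections, and
# the channel/spatial attention module (CBAM).
#
# Every block is a plain list of layers holding its own parameter
# environments; `block_forward()` runs it (optionally on a gradient tape) and
# `weight_count()` enumerates its parameters layer by layer.

# ---- primitive layers ------------------------------------------------------

# standard convolution layer, stride 1, same padding; init_sd overrides the
# He scale (the classification head uses a near-zero init so an untrained
# model predicts close to uniform)
new_conv_layer <- function(K, cin, cout, bn = TRUE, act = "relu", bias = TRUE,
                           init_sd = NULL) {
  sd <- if (is.null(init_sd)) sqrt(2 / (K * K * cin)) else init_sd
  l <- list(
    kind = "conv", K = as.integer(K), cin = cin, cout = cout, act = act,
    w = new_param(c(K * K, cin, cout), sd = sd),
    b = if (bias) new_param(cout, val = numeric(cout)) else NULL
  )
  if (bn) {
    l$bn <- list(gamma = new_param(cout, val = rep(1, cout)),
                 beta = new_param(cout, val = numeric(cout)),
                 state = new_bn_state(cout))
  }
  l
}

# depth-wise separable convolution: K x K depthwise stage (linear, with bias)
# followed by a 1x1 pointwise stage with BN + ReLU
new_dsc_layer <- function(cin, cout, K = 3L, bn = TRUE, act = "relu", bias = TRUE) {
  l <- list(
    kind = "dsc", K = as.integer(K), cin = cin, cout = cout, act = act,
    dw = new_param(c(K * K, cin), sd = sqrt(2 / (K * K))),
    dwb = if (bias) new_param(cin, val = numeric(cin)) else NULL,
    pw = new_param(c(1, cin, cout), sd = sqrt(2 / cin)),
    pwb = if (bias) new_param(cout, val = numeric(cout)) else NULL
  )
  if (bn) {
    l$bn <- list(gamma = new_param(cout, val = rep(1, cout)),
                 beta = new_param(cout, val = numeric(cout)),
                 state = new_bn_state(cout))
  }
  l
}

.apply_act <- function(tp, x, act) {
  switch(act, relu = op_relu(tp, x), sigmoid = op_sigmoid(tp, x), x)
}

.run_layer <- function(l, tp, x, training) {
  if (l$kind == "conv") {
    y <- op_conv(tp, x, .leaf_param(tp, l$w),
                 if (is.null(l$b)) NULL else .leaf_param(tp, l$b), l$K)
  } else if (l$kind == "dsc") {
    y <- op_dwconv(tp, x, .leaf_param(tp, l$dw),
                   if (is.null(l$dwb)) NULL else .leaf_param(tp, l$dwb), l$K)
    y <- op_conv(tp, y, .leaf_param(tp, l$pw),
                 if (is.null(l$pwb)) NULL else .leaf_param(tp, l$pwb), 1L)
  } else stop("unknown layer kind ", l$kind)
  if (!is.null(l$bn)) {
    y <- op_bn(tp, y, .leaf_param(tp, l$bn$gamma), .leaf_param(tp, l$bn$beta),
               l$bn$state, training)
  }
  .apply_act(tp, y, l$act)
}

# ---- block constructors ----------------------------------------------------

#' Depth-wise separable convolution block
#'
#' Factorizes a K x K convolution into a per-channel spatial stage and a 1x1
#' cross-channel stage, cutting kernel weights from K^2*Cin*N to
#' K^2*Cin + Cin*N. The depthwise stage is linear; batch normalization and
#' ReLU follow the pointwise stage.
#'
#' @param cin input channel count.
#' @param n filter count (output channels).
#' @param k kernel size (odd; default 3).
#' @param seed optional seed for weight initialization.
#' @return a `dsc_block` object.
#' @export
dsc_block <- function(cin, n, k = 3L, seed = NULL) {
  if (n < 1) stop("filter count n must be >= 1")
  if (k %% 2 != 1) stop("kernel size must be odd")
  mk <- function() structure(list(layer = new_dsc_layer(cin, n, k)),
                             class = c("dsc_block", "cauc_block"))
  if (is.null(seed)) mk() else .with_seed(seed, mk())
}

#' Linear Concatenated Block
#'
#' The residual-style block at the heart of the network. Dataflow:
#' `C1 = DSC(input)`; `CU1 = concat(input, C1)`; `P1 = 1x1(CU1)` with N/2
#' filters; dropout; `C2 = DSC(P1)`; `CU2 = concat(P1, C2)`; `P2 = 1x1(CU2)`
#' with N/2 filters; dropout; `C3 = DSC(P2)` giving the block's N output
#' channels at unchanged spatial extent.
#'
#' @param n filter allocation of the block (even).
#' @param ni input channel count.
#' @param dropout elementwise dropout rate applied after each 1x1 layer.
#' @param seed optional seed for weight initialization.
#' @return an `lcb_block` object.
#' @export
lcb_block <- function(n, ni, dropout = 0.1, seed = NULL) {
  if (n %% 2 != 0) stop("filter allocation n must be even")
  mk <- function() structure(list(
    n = n, ni = ni, dropout = dropout,
    d1 = new_dsc_layer(ni, n),
    p1 = new_conv_layer(1L, ni + n, n / 2),
    d2 = new_dsc_layer(n / 2, n),
    p2 = new_conv_layer(1L, n + n / 2, n / 2),
    d3 = new_dsc_layer(n / 2, n)
  ), class = c("lcb_block", "cauc_block"))
  if (is.null(seed)) mk() else .with_seed(seed, mk())
}

#' Attention gate for skip connections
#'
#' Gates an encoder skip feature X (N x N x M) with the coarser, deeper
#' feature Y (N/2 x N/2 x 2M): both are projected to `inter` channels by 1x1
#' convolutions (Y's projection is upsampled to X's grid), added, passed
#' through ReLU, reduced to a single channel, and squashed by a sigmoid into
#' a per-pixel gate in (0,1). The gated X passes through an output 1x1
#' transform back to M channels, giving the refined map RF of X's shape.
#'
#' @param m channel count of X.
#' @param inter projection width (defaults to `m`).
#' @param seed optional seed for weight initialization.
#' @return an `ag_block` object.
#' @export
ag_block <- function(m, inter = m, seed = NULL) {
  mk <- function() structure(list(
    m = m, inter = inter,
    wx = new_conv_layer(1L, m, inter, bn = TRUE, act = "none"),
    wy = new_conv_layer(1L, 2 * m, inter, bn = TRUE, act = "none"),
    psi = new_conv_layer(1L, inter, 1L, bn = TRUE, act = "none"),
    wout = new_conv_layer(1L, m, m, bn = TRUE, act = "none")
  ), class = c("ag_block", "cauc_block"))
  if (is.null(seed)) mk() else .with_seed(seed, mk())
}

#' Convolutional block attention module (CBAM)
#'
#' Sequential channel-then-spatial attention. The channel map (1 x 1 x C) is
#' `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared one-hidden-layer
#' MLP bottlenecked by `reduction`; the spatial map (H x W x 1) is a sigmoid
#' of a 7 x 7 convolution over the channel-wise average and maximum planes of
#' the channel-refined map. Both apply multiplicatively; the output keeps the
#' input shape.
#'
#' @param c channel count (must be divisible by `reduction`).
#' @param reduction MLP bottleneck divisor (default 8).
#' @param spatial_k spatial kernel size (odd; default 7).
#' @param seed optional seed for weight initialization.
#' @return a `cbam_block` object.
#' @export
cbam_block <- function(c, reduction = 8L, spatial_k = 7L, seed = NULL) {
  if (c %% reduction != 0) stop("reduction ratio must divide the channel count")
  if (spatial_k %% 2 != 1) stop("spatial kernel size must be odd")
  hid <- c %/% reduction
  mk <- function() structure(list(
    c = c, reduction = reduction,
    w1 = new_param(c(c, hid), sd = sqrt(2 / c)),
    b1 = new_param(hid, val = numeric(hid)),
    w2 = new_param(c(hid, c), sd = sqrt(2 / hid)),
    b2 = new_param(c, val = numeric(c)),
    sp = new_conv_layer(spatial_k, 2L, 1L, bn = FALSE, act = "none")
  ), class = c("cbam_block", "cauc_block"))
  if (is.null(seed)) mk() else .with_seed(seed, mk())
}

# ---- forward ---------------------------------------------------------------

#' Run a block forward
#'
#' @param block a block built by [dsc_block()], [lcb_block()], [ag_block()] or
#'   [cbam_block()].
#' @param x input feature map, H x W x C array (for the attention gate, the
#'   skip feature X).
#' @param ... further arguments: `y` (deeper feature) for the attention gate;
#'   `return_maps = TRUE` on attention blocks to also get the gate maps.
#' @param training logical; enables dropout and batch statistics.
#' @param tape internal gradient tape (NULL for plain evaluation).
#' @return the output feature map (or a list when `return_maps = TRUE`).
#' @export
block_forward <- function(block, x, ..., training = FALSE, tape = NULL) {
  UseMethod("block_forward")
}

#' @export
block_forward.dsc_block <- function(block, x, ..., training = FALSE, tape = NULL) {
  .check_channels(x, block$layer$cin)
  .ret(.run_layer(block$layer, tape, x, training), tape)
}

#' @export
block_forward.lcb_block <- function(block, x, ..., training = FALSE, tape = NULL) {
  .check_channels(x, block$ni)
  tp <- tape
  c1 <- .run_layer(block$d1, tp, x, training)
  cu1 <- op_concat(tp, list(x, c1))
  p1 <- .run_layer(block$p1, tp, cu1, training)
  if (training && block$dropout > 0) p1 <- op_dropout(tp, p1, block$dropout)
  c2 <- .run_layer(block$d2, tp, p1, training)
  cu2 <- op_concat(tp, list(p1, c2))
  p2 <- .run_layer(block$p2, tp, cu2, training)
  if (training && block$dropout > 0) p2 <- op_dropout(tp, p2, block$dropout)
  .ret(.run_layer(block$d3, tp, p2, training), tp)
}

#' @export
block_forward.ag_block <- function(block, x, y, ..., return_maps = FALSE,
                                   training = FALSE, tape = NULL) {
  dx <- dim(.v(x)); dy <- dim(.v(y))
  if (dy[1] * 2L != dx[1] || dy[2] * 2L != dx[2] || dy[3] != 2L * dx[3]) {
    stop(sprintf(
      "attention gate expects Y at half of X's grid with twice its channels; got X %dx%dx%d, Y %dx%dx%d",
      dx[1], dx[2], dx[3], dy[1], dy[2], dy[3]
    ))
  }
  .check_channels(x, block$m)
  tp <- tape
  xp <- .run_layer(block$wx, tp, x, training)
  yp <- op_upsample(tp, .run_layer(block$wy, tp, y, training), 2L)
  q <- op_relu(tp, op_add(tp, xp, yp))
  gate <- op_sigmoid(tp, .run_layer(block$psi, tp, q, training))
  rf <- .run_layer(block$wout, tp, op_mul_spatial(tp, x, gate), training)
  if (return_maps) list(rf = .v(rf), gate = .v(gate), node = rf) else .ret(rf, tp)
}

#' @export
block_forward.cbam_block <- function(block, x, ..., return_maps = FALSE,
                                     training = FALSE, tape = NULL) {
  .check_channels(x, block$c)
  tp <- tape
  mlp <- function(v) {
    h <- op_relu(tp, op_dense(tp, v, .leaf_param(tp, block$w1), .leaf_param(tp, block$b1)))
    op_dense(tp, h, .leaf_param(tp, block$w2), .leaf_param(tp, block$b2))
  }
  mch <- op_sigmoid(tp, op_add(tp, mlp(op_gap(tp, x)), mlp(op_gmp(tp, x))))
  f1 <- op_mul_channel(tp, x, mch)
  pooled <- op_concat(tp, list(op_chmean(tp, f1), op_chmax(tp, f1)))
  msp <- op_sigmoid(tp, .run_layer(block$sp, tp, pooled, training))
  out <- op_mul_spatial(tp, f1, msp)
  if (return_maps) list(out = .v(out), channel_map = .v(mch), spatial_map = .v(msp), node = out)
  else .ret(out, tp)
}

.check_channels <- function(x, expected) {
  got <- dim(.v(x))[3]
  if (got != expected) {
    stop(sprintf("input has %d channels; block expects %d", got, expected))
  }
}

# return bare array unless caller supplied a tape
.ret <- function(x, tp) if (is.null(tp)) x else x

# ---- parameter enumeration -------------------------------------------------

# all layer objects (kind == conv/dsc) nested anywhere in a block/model piece
.collect_layers <- function(x) {
  if (is.list(x) && !is.null(x$kind) && x$kind %in% c("conv", "dsc")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, .collect_layers)))
  list()
}

# all trainable parameter environments in a block/model piece
.collect_params <- function(x) {
  out <- list()
  rec <- function(y) {
    if (is.environment(y)) { out[[length(out) + 1L]] <<- y; return(invisible()) }
    if (is.list(y)) for (el in y) {
      if (is.environment(el) && !is.null(el$val)) out[[length(out) + 1L]] <<- el
      else if (is.list(el)) rec(el)
    }
  }
  rec(x)
  # drop BN running-state envs (they hold run_mean, not val)
  out[vapply(out, function(e) !is.null(e$val), TRUE)]
}

#' Count parameters of a block or model piece
#'
#' Enumerates parameters layer by layer. With the defaults this matches a
#' framework-style "total params" summary: convolution kernels, biases, batch
#' normalization scale/shift and running mean/variance, and attention MLP
#' weights. `include_bias = FALSE, include_bn = FALSE` counts kernel weights
#' only, the convention of the parameter-reduction calculus.
#'
#' @param x a block, layer or model.
#' @param include_bn count batch-norm scale/shift and running statistics.
#' @param include_bias count bias vectors.
#' @return integer parameter count.
#' @export
weight_count <- function(x, include_bn = TRUE, include_bias = TRUE) {
  UseMethod("weight_count")
}

#' @export
weight_count.default <- function(x, include_bn = TRUE, include_bias = TRUE) {
  layers <- .collect_layers(x)
  tot <- 0
  for (l in layers) {
    if (l$kind == "conv") {
      tot <- tot + length(l$w$val)
      if (include_bias && !is.null(l$b)) tot <- tot + length(l$b$val)
    } else {
      tot <- tot + length(l$dw$val) + length(l$pw$val)
      if (include_bias) {
        if (!is.null(l$dwb)) tot <- tot + length(l$dwb$val)
        if (!is.null(l$pwb)) tot <- tot + length(l$pwb$val)
      }
    }
    if (include_bn && !is.null(l$bn)) {
      tot <- tot + 2L * length(l$bn$gamma$val) + 2L * length(l$bn$gamma$val)
    }
  }
  # dense parameters (attention MLPs) are not conv layers; count them directly
  for (cb in .collect_cbams(x)) {
    tot <- tot + length(cb$w1$val) + length(cb$w2$val)
    if (include_bias) tot <- tot + length(cb$b1$val) + length(cb$b2$val)
  }
  as.integer(tot)
}

# all cbam blocks nested anywhere in a structure
.collect_cbams <- function(x) {
  if (inherits(x, "cbam_block")) return(list(x))
  if (is.list(x)) {
    return(do.call(c, lapply(x, function(el) {
      if (is.list(el)) .collect_cbams(el) else list()
    })))
  }
  list()
}
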