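# Minimal reverse-mode engine on plain R arrays.
#
# Feature maps are H x W x C double arrays. Every op takes a tape `tp` as its
# first argument: with a tape, inputs/outputs are graph nodes (environments
# holding $val) and gradients can be pulled back through the recorded ops;
# with tp = NULL the same code runs tape-free on bare arrays (inference).
#
# Convolutions avoid the im2col blow-up: a K x K convolution is computed as a
# sum over the K^2 spatial offsets of (shifted input) %*% (Cin x Cout weight
# slice), which keeps memory at O(HWC) and leans on BLAS.

.tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e
}

# create a node (or pass the bare value through when tp is NULL)
.nd <- function(tp, val, parents = list(), back = NULL, param = NULL) {
  if (is.null(tp)) return(val)
  n <- new.env(parent = emptyenv())
  n$val <- val; n$grad <- NULL; n$parents <- parents; n$back <- back; n$param <- param
  tp$nodes[[length(tp$nodes) + 1L]] <- n
  n
}

.v <- function(x) if (is.environment(x)) x$val else x

.acc <- function(n, g) {
  if (is.environment(n)) n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

# leaf node wrapping a trainable parameter
.leaf_param <- function(tp, p) .nd(tp, p$val, param = p)

#' @keywords internal
.backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in rev(seq_along(tp$nodes))) {
    n <- tp$nodes[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$back)) n$back(n)
    if (!is.null(n$param)) {
      n$param$grad <- if (is.null(n$param$grad)) n$grad else n$param$grad + n$grad
    }
  }
  invisible(NULL)
}

new_param <- function(dm, sd = NULL, val = NULL) {
  p <- new.env(parent = emptyenv())
  p$val <- if (!is.null(val)) val else array(stats::rnorm(prod(dm), 0, sd), dm)
  if (is.null(dim(p$val)) && length(dm) > 1) dim(p$val) <- dm
  p$grad <- NULL
  p$m <- NULL; p$v <- NULL  # Adam state
  p
}

# ---- shape helpers ---------------------------------------------------------

.as_mat <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
.as_arr <- function(m, h, w) { dim(m) <- c(h, w, ncol(m)); m }

# zero-padded shifted views of x for a K x K kernel: list of K^2 matrices
# (HW x C), offset order row-major over (dy, dx)
.shifts <- function(x, K) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]
  P <- (K - 1L) %/% 2L
  xp <- array(0, c(h + 2L * P, w + 2L * P, cc))
  xp[P + seq_len(h), P + seq_len(w), ] <- x
  out <- vector("list", K * K)
  k <- 0L
  for (dy in 0:(K - 1L)) for (dx in 0:(K - 1L)) {
    k <- k + 1L
    sl <- xp[dy + seq_len(h), dx + seq_len(w), , drop = FALSE]
    out[[k]] <- .as_mat(sl)
  }
  out
}

# scatter-add K^2 gradient matrices back onto the input grid
.unshift <- function(gs, K, h, w, cc) {
  P <- (K - 1L) %/% 2L
  gp <- array(0, c(h + 2L * P, w + 2L * P, cc))
  k <- 0L
  for (dy in 0:(K - 1L)) for (dx in 0:(K - 1L)) {
    k <- k + 1L
    if (is.null(gs[[k]])) next
    gp[dy + seq_len(h), dx + seq_len(w), ] <-
      gp[dy + seq_len(h), dx + seq_len(w), ] + .as_arr(gs[[k]], h, w)
  }
  gp[P + seq_len(h), P + seq_len(w), , drop = FALSE]
}

# ---- convolution ops -------------------------------------------------------

# standard convolution, stride 1, same padding
# w: array (K^2, Cin, Cout); b: length Cout or NULL
op_conv <- function(tp, x, w, b = NULL, K) {
  xv <- .v(x); wv <- .v(w); bv <- if (is.null(b)) NULL else .v(b)
  d <- dim(xv); h <- d[1]; ww <- d[2]; cin <- d[3]
  cout <- dim(wv)[3]
  sh <- .shifts(xv, K)
  out <- matrix(if (is.null(bv)) 0 else rep(bv, each = h * ww), h * ww, cout)
  for (k in seq_len(K * K)) {
    wk <- matrix(wv[k, , ], cin, cout)
    out <- out + sh[[k]] %*% wk
  }
  val <- .as_arr(out, h, ww)
  .nd(tp, val, parents = list(x, w, b), back = function(self) {
    g <- .as_mat(self$grad)
    gs <- vector("list", K * K)
    dw <- array(0, dim(wv))
    for (k in seq_len(K * K)) {
      wk <- matrix(wv[k, , ], cin, cout)
      gs[[k]] <- g %*% t(wk)
      dw[k, , ] <- crossprod(sh[[k]], g)
    }
    .acc(x, .unshift(gs, K, h, ww, cin))
    .acc(w, dw)
    if (!is.null(b)) .acc(b, colSums(g))
  })
}

# depthwise 3x3 convolution: w (9, C), b length C or NULL
op_dwconv <- function(tp, x, w, b = NULL, K = 3L) {
  xv <- .v(x); wv <- .v(w); bv <- if (is.null(b)) NULL else .v(b)
  d <- dim(xv); h <- d[1]; ww <- d[2]; cc <- d[3]
  sh <- .shifts(xv, K)
  out <- matrix(if (is.null(bv)) 0 else rep(bv, each = h * ww), h * ww, cc)
  for (k in seq_len(K * K)) out <- out + sh[[k]] * rep(wv[k, ], each = h * ww)
  val <- .as_arr(out, h, ww)
  .nd(tp, val, parents = list(x, w, b), back = function(self) {
    g <- .as_mat(self$grad)
    gs <- vector("list", K * K)
    dw <- array(0, dim(wv))
    for (k in seq_len(K * K)) {
      gs[[k]] <- g * rep(wv[k, ], each = h * ww)
      dw[k, ] <- colSums(sh[[k]] * g)
    }
    .acc(x, .unshift(gs, K, h, ww, cc))
    .acc(w, dw)
    if (!is.null(b)) .acc(b, colSums(g))
  })
}

# ---- normalization / activations ------------------------------------------

# batch normalization over the spatial positions of one sample
# state: env with run_mean, run_var (length C)
op_bn <- function(tp, x, gamma, beta, state, training, momentum = 0.9, eps = 1e-3) {
  xv <- .v(x); gv <- .v(gamma); bv <- .v(beta)
  d <- dim(xv); h <- d[1]; w <- d[2]; cc <- d[3]
  xm <- .as_mat(xv)
  n <- h * w
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    va <- colMeans(xc * xc)
    state$run_mean <- momentum * state$run_mean + (1 - momentum) * mu
    state$run_var <- momentum * state$run_var + (1 - momentum) * va
  } else {
    mu <- state$run_mean
    va <- state$run_var
    xc <- xm - rep(mu, each = n)
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * rep(ivar, each = n)
  ym <- xhat * rep(gv, each = n) + rep(bv, each = n)
  val <- .as_arr(ym, h, w)
  .nd(tp, val, parents = list(x, gamma, beta), back = function(self) {
    g <- .as_mat(self$grad)
    .acc(gamma, colSums(g * xhat))
    .acc(beta, colSums(g))
    dxhat <- g * rep(gv, each = n)
    if (training) {
      # standard batch-norm backward through the per-sample statistics
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rep(t1 / n, each = n) - xhat * rep(t2 / n, each = n)) *
        rep(ivar, each = n)
    } else {
      dx <- dxhat * rep(ivar, each = n)
    }
    .acc(x, .as_arr(dx, h, w))
  })
}

new_bn_state <- function(cc) {
  e <- new.env(parent = emptyenv())
  e$run_mean <- numeric(cc)
  e$run_var <- rep(1, cc)
  e
}

op_relu <- function(tp, x) {
  xv <- .v(x)
  mask <- xv > 0
  .nd(tp, xv * mask, parents = list(x),
      back = function(self) .acc(x, self$grad * mask))
}

op_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-.v(x)))
  .nd(tp, s, parents = list(x),
      back = function(self) .acc(x, self$grad * s * (1 - s)))
}

op_add <- function(tp, a, b) {
  .nd(tp, .v(a) + .v(b), parents = list(a, b), back = function(self) {
    .acc(a, self$grad); .acc(b, self$grad)
  })
}

# multiply a feature map by a per-channel gate (length C)
op_mul_channel <- function(tp, x, a) {
  xv <- .v(x); av <- .v(a)
  d <- dim(xv); n <- d[1] * d[2]
  xm <- .as_mat(xv)
  val <- .as_arr(xm * rep(av, each = n), d[1], d[2])
  .nd(tp, val, parents = list(x, a), back = function(self) {
    g <- .as_mat(self$grad)
    .acc(x, .as_arr(g * rep(av, each = n), d[1], d[2]))
    .acc(a, colSums(g * xm))
  })
}

# multiply a feature map by a spatial gate (H x W x 1)
op_mul_spatial <- function(tp, x, s) {
  xv <- .v(x); sv <- .v(s)
  d <- dim(xv)
  svec <- as.vector(sv)
  xm <- .as_mat(xv)
  val <- .as_arr(xm * svec, d[1], d[2])
  .nd(tp, val, parents = list(x, s), back = function(self) {
    g <- .as_mat(self$grad)
    .acc(x, .as_arr(g * svec, d[1], d[2]))
    .acc(s, array(rowSums(g * xm), c(d[1], d[2], 1)))
  })
}

op_concat <- function(tp, xs) {
  vals <- lapply(xs, .v)
  d <- dim(vals[[1]])
  ccs <- vapply(vals, function(v) dim(v)[3], 1L)
  val <- array(0, c(d[1], d[2], sum(ccs)))
  at <- 0L
  for (i in seq_along(vals)) {
    val[, , at + seq_len(ccs[i])] <- vals[[i]]
    at <- at + ccs[i]
  }
  .nd(tp, val, parents = xs, back = function(self) {
    at <- 0L
    for (i in seq_along(xs)) {
      .acc(xs[[i]], self$grad[, , at + seq_len(ccs[i]), drop = FALSE])
      at <- at + ccs[i]
    }
  })
}

# ---- resampling ops --------------------------------------------------------

op_maxpool2 <- function(tp, x) {
  xv <- .v(x)
  d <- dim(xv); h <- d[1]; w <- d[2]; cc <- d[3]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  i1 <- seq(1L, h, 2L); j1 <- seq(1L, w, 2L)
  v <- list(
    xv[i1, j1, , drop = FALSE], xv[i1 + 1L, j1, , drop = FALSE],
    xv[i1, j1 + 1L, , drop = FALSE], xv[i1 + 1L, j1 + 1L, , drop = FALSE]
  )
  val <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
  # first-wins argmax masks for the backward scatter
  b1 <- v[[1]] == val
  b2 <- (v[[2]] == val) & !b1
  b3 <- (v[[3]] == val) & !b1 & !b2
  b4 <- !(b1 | b2 | b3)
  .nd(tp, val, parents = list(x), back = function(self) {
    g <- self$grad
    dx <- array(0, d)
    dx[i1, j1, ] <- g * b1
    dx[i1 + 1L, j1, ] <- dx[i1 + 1L, j1, ] + g * b2
    dx[i1, j1 + 1L, ] <- dx[i1, j1 + 1L, ] + g * b3
    dx[i1 + 1L, j1 + 1L, ] <- dx[i1 + 1L, j1 + 1L, ] + g * b4
    .acc(x, dx)
  })
}

# parameter-free nearest-neighbour upsampling by integer factor s
op_upsample <- function(tp, x, s) {
  xv <- .v(x)
  d <- dim(xv); h <- d[1]; w <- d[2]; cc <- d[3]
  val <- xv[rep(seq_len(h), each = s), rep(seq_len(w), each = s), , drop = FALSE]
  .nd(tp, val, parents = list(x), back = function(self) {
    g <- self$grad
    dim(g) <- c(s, h, s * w * cc)
    g1 <- colSums(g)                   # (h, s*w*cc)
    dim(g1) <- c(h, s, w, cc)
    g2 <- aperm(g1, c(2, 1, 3, 4))     # (s, h, w, cc)
    dim(g2) <- c(s, h * w * cc)
    dx <- colSums(g2)
    dim(dx) <- c(h, w, cc)
    .acc(x, dx)
  })
}

# ---- pooling descriptors (CBAM) -------------------------------------------

# global average pool -> length-C vector
op_gap <- function(tp, x) {
  xv <- .v(x); d <- dim(xv); n <- d[1] * d[2]
  val <- colMeans(.as_mat(xv))
  .nd(tp, val, parents = list(x), back = function(self) {
    g <- matrix(rep(self$grad / n, each = n), n, d[3])
    .acc(x, .as_arr(g, d[1], d[2]))
  })
}

# global max pool -> length-C vector
op_gmp <- function(tp, x) {
  xv <- .v(x); d <- dim(xv); n <- d[1] * d[2]
  xm <- .as_mat(xv)
  idx <- max.col(t(xm), ties.method = "first")
  val <- xm[cbind(idx, seq_len(d[3]))]
  .nd(tp, val, parents = list(x), back = function(self) {
    g <- matrix(0, n, d[3])
    g[cbind(idx, seq_len(d[3]))] <- self$grad
    .acc(x, .as_arr(g, d[1], d[2]))
  })
}

# per-pixel mean over channels -> H x W x 1
op_chmean <- function(tp, x) {
  xv <- .v(x); d <- dim(xv); cc <- d[3]
  val <- array(rowMeans(.as_mat(xv)), c(d[1], d[2], 1))
  .nd(tp, val, parents = list(x), back = function(self) {
    g <- matrix(rep(as.vector(self$grad) / cc, cc), d[1] * d[2], cc)
    .acc(x, .as_arr(g, d[1], d[2]))
  })
}

# per-pixel max over channels -> H x W x 1
op_chmax <- function(tp, x) {
  xv <- .v(x); d <- dim(xv)
  xm <- .as_mat(xv)
  idx <- max.col(xm, ties.method = "first")
  val <- array(xm[cbind(seq_len(nrow(xm)), idx)], c(d[1], d[2], 1))
  .nd(tp, val, parents = list(x), back = function(self) {
    g <- matrix(0, nrow(xm), d[3])
    g[cbind(seq_len(nrow(xm)), idx)] <- as.vector(self$grad)
    .acc(x, .as_arr(g, d[1], d[2]))
  })
}

# ---- dense / dropout / loss ------------------------------------------------

# fully connected on a length-Cin vector; w: (Cin, Cout)
op_dense <- function(tp, x, w, b = NULL) {
  xv <- .v(x); wv <- .v(w); bv <- if (is.null(b)) NULL else .v(b)
  val <- as.vector(xv %*% wv)
  if (!is.null(bv)) val <- val + bv
  .nd(tp, val, parents = list(x, w, b), back = function(self) {
    g <- self$grad
    .acc(x, as.vector(wv %*% g))
    .acc(w, outer(xv, g))
    if (!is.null(b)) .acc(b, g)
  })
}

# dropout; channelwise=TRUE drops whole feature channels ("drop channel")
op_dropout <- function(tp, x, rate, channelwise = FALSE) {
  if (rate <= 0) return(x)
  xv <- .v(x); d <- dim(xv)
  keep <- 1 - rate
  if (channelwise) {
    mc <- (stats::runif(d[3]) < keep) / keep
    mask <- array(rep(mc, each = d[1] * d[2]), d)
  } else {
    mask <- array((stats::runif(prod(d)) < keep) / keep, d)
  }
  .nd(tp, xv * mask, parents = list(x),
      back = function(self) .acc(x, self$grad * mask))
}

# per-pixel softmax over channels
softmax3 <- function(z) {
  d <- dim(z)
  m <- .as_mat(z)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  .as_arr(e / rowSums(e), d[1], d[2])
}

# fused per-pixel softmax + categorical cross-entropy (mean over pixels)
op_softmax_ce <- function(tp, logits, target) {
  zv <- .v(logits)
  p <- softmax3(zv)
  n <- dim(zv)[1] * dim(zv)[2]
  loss <- -sum(target * log(pmax(.as_mat(p), 1e-12))) / n
  .nd(tp, loss, parents = list(logits), back = function(self) {
    g <- (.as_mat(p) - target) / n * self$grad
    .acc(logits, .as_arr(g, dim(zv)[1], dim(zv)[2]))
  })
}

# ---- Adam ------------------------------------------------------------------

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      scale = 1) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad * scale
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
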