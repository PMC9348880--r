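# Minimal convolutional network engine used by the TTC auto-encoder.
#
# Feature maps are stored sample-major as (H*W*N) x C matrices: rows are
# pixels (column-major over (y, x)) for sample 1, then sample 2, ...;
# columns are channels. In this layout a convolution evaluated via im2col
# needs no output reshape at all: the im2col matrix is a single row-gather
# of the zero-padded input (with indices precomputed per batch size and
# cached on the layer plan), the product with the (k*k*C_in) x C_out
# weight matrix is one BLAS call, and its result is already the output
# plane. Backward passes reuse the same index tables; scatter-adds are
# organised per kernel offset, where target rows are duplicate-free, so no
# aggregation primitive is needed. Only what the auto-encoder requires is
# implemented: 3x3 convolutions (stride 1 or 2, zero padding 1), ReLU,
# nearest-neighbour 2x upsampling, global average pooling, dense layers.

make_conv_plan <- function(h, k = 3, stride = 1, pad = 1) {
  hp <- h + 2 * pad
  ho <- (hp - k) %/% stride + 1
  oy <- rep(seq_len(ho), times = ho)   # output pixel, oy fastest
  ox <- rep(seq_len(ho), each = ho)
  y0 <- (oy - 1) * stride + 1
  x0 <- (ox - 1) * stride + 1
  kk <- k * k
  # idx[, kidx]: padded-plane row read by kernel offset kidx at each output
  # pixel; kidx ordered dy fastest then dx, matching the weight row order
  idx <- matrix(0L, ho * ho, kk)
  for (dx in 0:(k - 1)) {
    for (dy in 0:(k - 1)) {
      idx[, dx * k + dy + 1L] <- (x0 + dx - 1L) * hp + (y0 + dy)
    }
  }
  yy <- rep(seq_len(h), times = h)
  xx <- rep(seq_len(h), each = h)
  pad_idx <- (xx + pad - 1L) * hp + (yy + pad)
  list(h = h, hp = hp, ho = ho, k = k, kk = kk, np = hp * hp,
       howo = ho * ho, idx = idx, pad_idx = pad_idx,
       memo = new.env(parent = emptyenv()))
}

# Batch-size-dependent index tables, memoised on the plan.
conv_rows <- function(plan, n) {
  key <- paste0("n", n)
  got <- plan$memo[[key]]
  if (!is.null(got)) return(got)
  np_off <- rep((seq_len(n) - 1L) * plan$np, each = plan$howo)
  # gather rows ordered (output pixel, sample) fastest, kernel offset slowest
  gather <- integer(plan$howo * n * plan$kk)
  scatter <- vector("list", plan$kk)
  blk <- plan$howo * n
  for (kidx in seq_len(plan$kk)) {
    rows_k <- rep(plan$idx[, kidx], times = n) + np_off
    gather[(kidx - 1L) * blk + seq_len(blk)] <- rows_k
    scatter[[kidx]] <- rows_k
  }
  pad_rows <- rep(plan$pad_idx, times = n) +
    rep((seq_len(n) - 1L) * plan$np, each = plan$h * plan$h)
  got <- list(gather = gather, scatter = scatter, pad_rows = pad_rows)
  plan$memo[[key]] <- got
  got
}

conv_forward <- function(p, w, b, plan, c_in, c_out, n) {
  rows <- conv_rows(plan, n)
  ppad <- matrix(0, plan$np * n, c_in)
  ppad[rows$pad_rows, ] <- p
  m <- ppad[rows$gather, , drop = FALSE]
  dim(m) <- c(plan$howo * n, plan$kk * c_in)
  out <- m %*% w
  out <- sweep(out, 2, b, `+`)
  list(out = out, m = m)
}

conv_backward <- function(dout, m, w, plan, c_in, c_out, n) {
  rows <- conv_rows(plan, n)
  dw <- crossprod(m, dout)
  db <- colSums(dout)
  dm <- tcrossprod(dout, w)                  # (howo*n) x (kk*c_in)
  dppad <- matrix(0, plan$np * n, c_in)
  cols0 <- (seq_len(c_in) - 1L) * plan$kk
  for (kidx in seq_len(plan$kk)) {
    rk <- rows$scatter[[kidx]]               # duplicate-free target rows
    dppad[rk, ] <- dppad[rk, , drop = FALSE] +
      dm[, cols0 + kidx, drop = FALSE]
  }
  list(dp = dppad[rows$pad_rows, , drop = FALSE], dw = dw, db = db)
}

make_up_plan <- function(h) {
  ho <- 2L * h
  y <- rep(seq_len(ho), times = ho)
  x <- rep(seq_len(ho), each = ho)
  idx <- (ceiling(x / 2) - 1L) * h + ceiling(y / 2)
  # partition output pixels into the four parity classes; within each the
  # map back to input pixels is a bijection, ordered like the input rows
  iy <- rep(seq_len(h), times = h)
  ix <- rep(seq_len(h), each = h)
  par <- vector("list", 4)
  j <- 1L
  for (dx in 0:1) {
    for (dy in 0:1) {
      par[[j]] <- (2L * ix - 2L + dx) * ho + (2L * iy - 1L + dy)
      j <- j + 1L
    }
  }
  list(h = h, ho = ho, hw = h * h, howo = ho * ho, idx = idx, par = par,
       memo = new.env(parent = emptyenv()))
}

up_rows <- function(plan, n) {
  key <- paste0("n", n)
  got <- plan$memo[[key]]
  if (!is.null(got)) return(got)
  fwd <- rep(plan$idx, times = n) +
    rep((seq_len(n) - 1L) * plan$hw, each = plan$howo)
  par <- lapply(plan$par, function(pk) {
    rep(pk, times = n) + rep((seq_len(n) - 1L) * plan$howo, each = plan$hw)
  })
  got <- list(fwd = fwd, par = par)
  plan$memo[[key]] <- got
  got
}

up_forward <- function(p, plan, n) {
  p[up_rows(plan, n)$fwd, , drop = FALSE]
}

up_backward <- function(dout, plan, n) {
  rows <- up_rows(plan, n)
  dp <- dout[rows$par[[1]], , drop = FALSE]
  for (j in 2:4) dp <- dp + dout[rows$par[[j]], , drop = FALSE]
  dp
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Global average pool: (hw*n) x c plane -> (n, c)
gap_forward <- function(p, hw, c, n) {
  matrix(.colMeans(p, hw, n * c), n, c)
}

gap_backward <- function(dz, hw, c, n) {
  dz[rep(seq_len(n), each = hw), , drop = FALSE] / hw
}

# 2x average pooling (the reverse of nearest-neighbour upsampling); the
# plan argument is an up-plan for the *output* side length.
pool2_forward <- function(p, plan, n) {
  up_backward(p, plan, n) / 4
}

pool2_backward <- function(dout, plan, n) {
  up_forward(dout, plan, n) / 4
}

he_init <- function(nin, nout, gain = 2) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(gain / nin)), nin, nout)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
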