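# Low-level neural network operations --------------------------------------
#
# The classifier is a self-contained network implementation built on BLAS
# matrix products. Batched 1-D convolution uses an im2col layout: a batch
# of B frames of length L with C channels is one (L*B) x C matrix whose
# rows are frame-major (row = t + (b-1)*L); every convolution then becomes
# a single gemm against a (k*C) x F weight matrix. All backward passes are
# hand-derived and verified against finite differences in the test suite.

conv_out_len <- function(L, k, stride, pad) {
  (L + 2L * pad - k) %/% stride + 1L
}

# index matrix mapping output positions to input rows; rows of the result
# are (position, frame) pairs, columns are kernel taps. Out-of-range taps
# point one past the input (L*B + 1), which the C++ kernels read as zero.
# Index matrices recur for every batch of the same geometry, so they are
# memoized.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_index <- function(L, B, k, stride, pad) {
  key <- paste(L, B, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  L_out <- conv_out_len(L, k, stride, pad)
  zero_row <- L * B + 1L
  idx <- matrix(0L, L_out * B, k)
  frame_off <- (seq_len(B) - 1L) * L
  for (j in seq_len(k)) {
    tj <- (seq_len(L_out) - 1L) * stride + j - pad
    m <- outer(tj, frame_off, "+")
    m[tj < 1L | tj > L, ] <- zero_row
    idx[, j] <- as.vector(m)
  }
  if (length(ls(.conv_idx_cache)) > 24)
    rm(list = ls(.conv_idx_cache), envir = .conv_idx_cache)
  .conv_idx_cache[[key]] <- idx
  idx
}

conv_fwd <- function(x, W, b, L, B, k, stride, pad) {
  C <- ncol(x)
  idx <- conv_index(L, B, k, stride, pad)
  N <- nrow(idx)
  P <- cpp_gather_patches(x, idx)           # N x (k*C), tap fastest
  out <- P %*% W
  out <- out + rep(b, each = N)
  list(out = out, cache = list(P = P, idx = idx, W = W, L = L, B = B,
                               C = C, k = k))
}

conv_bwd <- function(dout, cache) {
  N <- nrow(dout)
  dW <- crossprod(cache$P, dout)
  db <- colSums(dout)
  dP <- dout %*% t(cache$W)                 # N x (k*C)
  dx <- cpp_scatter_patches(dP, cache$idx, cache$L * cache$B, cache$C)
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization per channel (column), over all positions and frames.
bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.9,
                   eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  ap <- cpp_bn_apply(x, mu, inv_sd, gamma, beta)
  list(out = ap$out, state = state,
       cache = list(xhat = ap$xhat, inv_sd = inv_sd, gamma = gamma,
                    training = training))
}

bn_bwd <- function(dout, cache) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  a <- cache$gamma * cache$inv_sd
  if (cache$training) {
    m1 <- colMeans(dout)
    m2 <- colMeans(dout * cache$xhat)
  } else {
    m1 <- numeric(length(a))
    m2 <- numeric(length(a))
  }
  dx <- cpp_bn_dx(dout, cache$xhat, m1, m2, a)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dout, out) dout * (out > 0)

# Non-overlapping max pooling along time within each frame; trailing
# positions that do not fill a window are dropped. Ties route the gradient
# to the first tap.
maxpool_fwd <- function(x, L, B, pool) {
  Lp <- L %/% pool
  base <- outer(pool * (seq_len(Lp) - 1L), (seq_len(B) - 1L) * L, "+")
  idx <- lapply(seq_len(pool), function(j) as.vector(base) + j)
  out <- x[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(out), ncol(out))
  for (j in seq_along(idx)[-1]) {
    s <- x[idx[[j]], , drop = FALSE]
    better <- s > out
    out[better] <- s[better]
    arg[better] <- j
  }
  list(out = out,
       cache = list(idx = idx, arg = arg, L = L, B = B, C = ncol(x)))
}

maxpool_bwd <- function(dout, cache) {
  dx <- matrix(0, cache$L * cache$B, cache$C)
  for (j in seq_along(cache$idx))
    dx[cache$idx[[j]], ] <- dout * (cache$arg == j)
  dx
}

# Global average pooling: one embedding per frame.
gap_fwd <- function(x, L, B) {
  group <- rep(seq_len(B), each = L)
  out <- rowsum(x, group) / L
  list(out = out, cache = list(L = L, B = B, group = group))
}

gap_bwd <- function(dout, cache) {
  dout[cache$group, , drop = FALSE] / cache$L
}

# He-style initialization for conv weights, small uniform for recurrent.
init_conv <- function(k, C, F_out) {
  matrix(stats::rnorm(k * C * F_out, 0, sqrt(2 / (k * C))), k * C, F_out)
}

init_uniform <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# Adam optimizer over a nested (one-level) list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
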