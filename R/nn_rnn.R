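# LSTM, bidirectional wrapper, and additive attention ----------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM direction over a sequence of T matrices (R records x d inputs).
# Gate layout in the (d+h) x 4h weight matrix: input, forget, cell, output.
lstm_fwd <- function(xs, W, b, h_units) {
  T_len <- length(xs)
  R <- nrow(xs[[1]])
  h <- matrix(0, R, h_units)
  cc <- matrix(0, R, h_units)
  hs <- vector("list", T_len)
  caches <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    z <- cbind(xs[[t]], h) %*% W + rep(b, each = R)
    i_g <- sigmoid(z[, seq_len(h_units), drop = FALSE])
    f_g <- sigmoid(z[, h_units + seq_len(h_units), drop = FALSE])
    g_g <- tanh(z[, 2 * h_units + seq_len(h_units), drop = FALSE])
    o_g <- sigmoid(z[, 3 * h_units + seq_len(h_units), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    caches[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cc, i = i_g,
                        f = f_g, g = g_g, o = o_g, c = c_new, tc = tc)
    h <- h_new
    cc <- c_new
    hs[[t]] <- h_new
  }
  list(hs = hs, caches = caches)
}

lstm_bwd <- function(dhs, caches, W, h_units) {
  T_len <- length(caches)
  R <- nrow(dhs[[1]])
  d_in <- ncol(caches[[1]]$x)
  dW <- W * 0
  db <- numeric(4 * h_units)
  dxs <- vector("list", T_len)
  dh_next <- matrix(0, R, h_units)
  dc_next <- matrix(0, R, h_units)
  for (t in rev(seq_len(T_len))) {
    ca <- caches[[t]]
    dh <- dhs[[t]] + dh_next
    do_g <- dh * ca$tc
    dc <- dh * ca$o * (1 - ca$tc^2) + dc_next
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_g * ca$o * (1 - ca$o))
    inp <- cbind(ca$x, ca$h_prev)
    dW <- dW + crossprod(inp, dz)
    db <- db + colSums(dz)
    dinp <- dz %*% t(W)
    dxs[[t]] <- dinp[, seq_len(d_in), drop = FALSE]
    dh_next <- dinp[, d_in + seq_len(h_units), drop = FALSE]
  }
  list(dxs = dxs, dW = dW, db = db)
}

bilstm_fwd <- function(xs, params, h_units) {
  fw <- lstm_fwd(xs, params$lstm_f_W, params$lstm_f_b, h_units)
  bw <- lstm_fwd(rev(xs), params$lstm_b_W, params$lstm_b_b, h_units)
  T_len <- length(xs)
  hs <- lapply(seq_len(T_len), function(t)
    cbind(fw$hs[[t]], bw$hs[[T_len - t + 1]]))
  list(hs = hs, fw = fw, bw = bw)
}

bilstm_bwd <- function(dhs, cache, params, h_units) {
  T_len <- length(dhs)
  dfw <- lapply(dhs, function(d) d[, seq_len(h_units), drop = FALSE])
  dbw <- lapply(rev(seq_len(T_len)), function(t)
    dhs[[t]][, h_units + seq_len(h_units), drop = FALSE])
  gf <- lstm_bwd(dfw, cache$fw$caches, params$lstm_f_W, h_units)
  gb <- lstm_bwd(dbw, cache$bw$caches, params$lstm_b_W, h_units)
  dxs <- lapply(seq_len(T_len), function(t)
    gf$dxs[[t]] + gb$dxs[[T_len - t + 1]])
  list(dxs = dxs, lstm_f_W = gf$dW, lstm_f_b = gf$db,
       lstm_b_W = gb$dW, lstm_b_b = gb$db)
}

# Additive attention over a sequence of hidden states: a learned query
# vector v scores tanh(H W + b) at each step, softmax normalizes the
# scores, and the context is the weighted sum of the states.
attention_fwd <- function(hs, Wa, ba, va) {
  T_len <- length(hs)
  R <- nrow(hs[[1]])
  us <- vector("list", T_len)
  S <- matrix(0, R, T_len)
  for (t in seq_len(T_len)) {
    u <- tanh(hs[[t]] %*% Wa + rep(ba, each = R))
    us[[t]] <- u
    S[, t] <- as.vector(u %*% va)
  }
  S <- S - apply(S, 1, max)
  E <- exp(S)
  alpha <- E / rowSums(E)
  context <- matrix(0, R, ncol(hs[[1]]))
  for (t in seq_len(T_len))
    context <- context + alpha[, t] * hs[[t]]
  list(context = context, alpha = alpha,
       cache = list(hs = hs, us = us, alpha = alpha, Wa = Wa, va = va))
}

attention_bwd <- function(dcontext, cache) {
  hs <- cache$hs
  alpha <- cache$alpha
  T_len <- length(hs)
  R <- nrow(dcontext)
  dalpha <- matrix(0, R, T_len)
  dhs <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    dalpha[, t] <- rowSums(dcontext * hs[[t]])
    dhs[[t]] <- alpha[, t] * dcontext
  }
  ds <- alpha * (dalpha - rowSums(dalpha * alpha))  # softmax jacobian
  dWa <- cache$Wa * 0
  dba <- numeric(ncol(cache$Wa))
  dva <- cache$va * 0
  for (t in seq_len(T_len)) {
    u <- cache$us[[t]]
    du <- (ds[, t] %o% cache$va) * (1 - u^2)
    dWa <- dWa + crossprod(hs[[t]], du)
    dba <- dba + colSums(du)
    dva <- dva + colSums(u * ds[, t])
    dhs[[t]] <- dhs[[t]] + du %*% t(cache$Wa)
  }
  list(dhs = dhs, Wa = dWa, ba = dba, va = dva)
}

#' Attention pooling of a sequence
#'
#' Collapses a sequence of feature vectors into one context vector by
#' additive attention: each step is scored by a learned query against
#' `tanh(W h + b)`, the scores are softmax-normalized into non-negative
#' weights summing to one, and the context is the weighted sum of steps.
#'
#' @param sequence Numeric matrix, steps x features.
#' @param params Optional list with `W` (features x attention_dim), `b`
#'   (attention_dim), `v` (attention_dim); drawn from `seed` when omitted.
#' @param attention_dim Scoring dimension when `params` is omitted.
#' @param seed Seed for the drawn parameters.
#' @return List with `context` (feature vector) and `weights` (one
#'   non-negative weight per step, summing to 1).
#' @examples
#' ap <- attention_pool(matrix(rnorm(5 * 4), 5, 4), seed = 1)
#' sum(ap$weights)  # 1
#' @export
attention_pool <- function(sequence, params = NULL, attention_dim = 8,
                           seed = 1L) {
  sequence <- as.matrix(sequence)
  if (nrow(sequence) < 1)
    stop_ecgfb("ecgfb_parameter_error", "sequence must have >= 1 step")
  d <- ncol(sequence)
  if (is.null(params)) {
    params <- with_seed(seed, list(
      W = init_uniform(d, attention_dim, 1 / sqrt(d)),
      b = numeric(attention_dim),
      v = stats::runif(attention_dim, -1, 1)))
  }
  hs <- lapply(seq_len(nrow(sequence)), function(t)
    matrix(sequence[t, ], 1, d))
  fwd <- attention_fwd(hs, params$W, params$b, params$v)
  list(context = as.vector(fwd$context), weights = as.vector(fwd$alpha))
}
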