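# Per-class classifier: per-frame residual CNN -> attention BiLSTM ---------

#' Classifier architecture and training configuration
#'
#' The network consumes a (frames x frame_length x leads) block. A shared
#' convolutional trunk is applied to every frame: initial Conv1D -> batch
#' norm -> ReLU -> max pool, then a residual block with an identity
#' shortcut, then a residual block with a projection (Conv1D + batch norm)
#' shortcut that doubles the channels and halves the time axis, then global
#' average pooling, yielding one embedding per frame. The embedding
#' sequence is read by a bidirectional LSTM, pooled by additive attention,
#' and a single sigmoid unit emits the class probability; training
#' minimizes binary cross-entropy with Adam.
#'
#' Counted by the convention documented in [layer_census()] (trunk Conv1D,
#' batch-norm and max-pool layers), the trunk has 13 layers.
#'
#' @param frames,frame_length,leads Expected input block shape.
#' @param initial_conv List `filters`, `kernel`, `stride` of the entry
#'   convolution.
#' @param block1 List `filters`, `kernel` of the identity-shortcut residual
#'   block (kernel must be odd).
#' @param block2 List `filters`, `kernel`, `stride` of the
#'   projection-shortcut residual block (kernel must be odd).
#' @param pool_size Max-pool window (default 3: the maximum of every three
#'   values is kept).
#' @param lstm_units Hidden units per LSTM direction.
#' @param attention_dim Additive-attention scoring dimension.
#' @param threshold Decision threshold on the sigmoid probability; a
#'   probability equal to the threshold is called positive.
#' @param epochs,batch_size,learning_rate,patience,seed Training
#'   hyperparameters; `batch_size` counts records, `patience` is the early
#'   stopping patience (epochs without validation improvement).
#' @return A `model_config` object.
#' @export
model_config <- function(frames = 10, frame_length = 2000, leads = 12,
                         initial_conv = list(filters = 32, kernel = 16,
                                             stride = 2),
                         block1 = list(filters = 32, kernel = 7),
                         block2 = list(filters = 64, kernel = 5,
                                       stride = 2),
                         pool_size = 3, lstm_units = 64,
                         attention_dim = 64, threshold = 0.5, epochs = 30,
                         batch_size = 8, learning_rate = 1e-3,
                         patience = 5, seed = 1L) {
  if (pool_size < 1)
    stop_ecgfb("ecgfb_parameter_error", "pool_size must be >= 1")
  if (threshold <= 0 || threshold >= 1)
    stop_ecgfb("ecgfb_parameter_error", "threshold must be in (0, 1)")
  sizes <- c(initial_conv$filters, initial_conv$kernel, block1$filters,
             block1$kernel, block2$filters, block2$kernel, lstm_units,
             attention_dim, frames, frame_length, leads)
  if (any(sizes < 1))
    stop_ecgfb("ecgfb_parameter_error", "all layer sizes must be positive")
  if (block1$kernel %% 2 == 0 || block2$kernel %% 2 == 0)
    stop_ecgfb("ecgfb_parameter_error",
               "residual block kernels must be odd (same-length padding)")
  structure(list(frames = as.integer(frames),
                 frame_length = as.integer(frame_length),
                 leads = as.integer(leads), initial_conv = initial_conv,
                 block1 = block1, block2 = block2,
                 pool_size = as.integer(pool_size),
                 lstm_units = as.integer(lstm_units),
                 attention_dim = as.integer(attention_dim),
                 threshold = threshold, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "model_config")
}

model_geometry <- function(cfg) {
  L1 <- conv_out_len(cfg$frame_length, cfg$initial_conv$kernel,
                     cfg$initial_conv$stride, 0L)
  L2 <- L1 %/% cfg$pool_size
  L3 <- conv_out_len(L2, cfg$block2$kernel, cfg$block2$stride,
                     (cfg$block2$kernel - 1L) %/% 2L)
  if (L1 < cfg$pool_size || L2 < 1 || L3 < 1)
    stop_ecgfb("ecgfb_construction_error",
               "frame_length %d too short for the configured trunk",
               cfg$frame_length)
  list(L1 = L1, L2 = L2, L3 = L3)
}

#' Build an untrained classifier
#'
#' Initializes all parameters from `config$seed`; the forward pass of the
#' returned handle is deterministic given its parameters.
#'
#' @param config A [model_config()].
#' @return An `ecgfb_model` handle (parameters, batch-norm statistics,
#'   config, empty training history).
#' @export
build_model <- function(config = model_config()) {
  geom <- model_geometry(config)
  ic <- config$initial_conv; b1 <- config$block1; b2 <- config$block2
  h <- config$lstm_units
  D <- 2L * h
  params <- with_seed(config$seed, {
    sc <- 1 / sqrt(h)
    list(
      conv0_W = init_conv(ic$kernel, config$leads, ic$filters),
      conv0_b = numeric(ic$filters),
      bn0_g = rep(1, ic$filters), bn0_b = numeric(ic$filters),
      b1c1_W = init_conv(b1$kernel, ic$filters, b1$filters),
      b1c1_b = numeric(b1$filters),
      b1bn1_g = rep(1, b1$filters), b1bn1_b = numeric(b1$filters),
      b1c2_W = init_conv(b1$kernel, b1$filters, b1$filters),
      b1c2_b = numeric(b1$filters),
      b1bn2_g = rep(1, b1$filters), b1bn2_b = numeric(b1$filters),
      b2c1_W = init_conv(b2$kernel, b1$filters, b2$filters),
      b2c1_b = numeric(b2$filters),
      b2bn1_g = rep(1, b2$filters), b2bn1_b = numeric(b2$filters),
      b2c2_W = init_conv(b2$kernel, b2$filters, b2$filters),
      b2c2_b = numeric(b2$filters),
      b2bn2_g = rep(1, b2$filters), b2bn2_b = numeric(b2$filters),
      b2sc_W = init_conv(1L, b1$filters, b2$filters),
      b2sc_b = numeric(b2$filters),
      b2scbn_g = rep(1, b2$filters), b2scbn_b = numeric(b2$filters),
      lstm_f_W = init_uniform(b2$filters + h, 4 * h, sc),
      lstm_f_b = rep(c(0, 1, 0, 0), each = h),  # forget-gate bias 1
      lstm_b_W = init_uniform(b2$filters + h, 4 * h, sc),
      lstm_b_b = rep(c(0, 1, 0, 0), each = h),
      att_Wa = init_uniform(D, config$attention_dim, 1 / sqrt(D)),
      att_ba = numeric(config$attention_dim),
      att_va = stats::runif(config$attention_dim, -0.5, 0.5),
      out_w = init_uniform(D, 1, 1 / sqrt(D)),
      out_b = 0)
  })
  bn_state <- function(nf) list(mean = numeric(nf), var = rep(1, nf))
  state <- list(bn0 = bn_state(ic$filters),
                b1bn1 = bn_state(b1$filters), b1bn2 = bn_state(b1$filters),
                b2bn1 = bn_state(b2$filters), b2bn2 = bn_state(b2$filters),
                b2scbn = bn_state(b2$filters))
  structure(list(params = params, state = state, config = config,
                 geom = geom, history = list(), trained = FALSE),
            class = "ecgfb_model")
}

#' @export
print.ecgfb_model <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf(
    "<ecgfb_model: input (%d, %d, %d), %d trunk layers, BiLSTM %d/dir, %s>\n",
    x$config$frames, x$config$frame_length, x$config$leads, cen$total,
    x$config$lstm_units, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Trunk layer census
#'
#' Counts the layers of the convolutional trunk by the convention
#' "convolutional + batch-normalization + max-pooling layers": the entry
#' Conv1D and its batch norm, the max pool, two Conv1D + batch-norm pairs
#' in the identity residual block, two in the projection residual block,
#' and the projection shortcut's Conv1D + batch norm — 6 convolutions,
#' 6 batch norms and 1 pool, i.e. 13 layers for any configuration.
#'
#' @param model An `ecgfb_model` or [model_config()].
#' @return List with `conv`, `batch_norm`, `max_pool`, `total`.
#' @export
layer_census <- function(model) {
  n_conv <- sum(grepl("^(conv0|b1c[12]|b2c[12]|b2sc)_W$",
                      names(if (inherits(model, "ecgfb_model"))
                        model$params else build_model(model)$params)))
  n_bn <- n_conv  # every trunk convolution is followed by a batch norm
  list(conv = n_conv, batch_norm = n_bn, max_pool = 1L,
       total = n_conv + n_bn + 1L)
}

# Stack a list of frame blocks into the frame-major (L*B) x C im2col input
# layout; b = frame + (record-1)*frames.
assemble_input <- function(blocks, cfg) {
  R <- length(blocks)
  for (fb in blocks) {
    d <- dim(fb$data)
    if (!all(d == c(cfg$frames, cfg$frame_length, cfg$leads)))
      stop_ecgfb("ecgfb_construction_error",
                 "block %s has shape (%s) but the model expects (%d, %d, %d)",
                 fb$source_id, paste(d, collapse = ", "), cfg$frames,
                 cfg$frame_length, cfg$leads)
  }
  L <- cfg$frame_length; Fn <- cfg$frames; C <- cfg$leads
  big <- array(0, c(L, Fn * R, C))
  for (r in seq_len(R))
    big[, (r - 1) * Fn + seq_len(Fn), ] <- aperm(blocks[[r]]$data,
                                                 c(2, 1, 3))
  dim(big) <- c(L * Fn * R, C)
  list(x = big, R = R, B = Fn * R)
}

cnn_forward <- function(x, params, state, cfg, geom, B, training) {
  ic <- cfg$initial_conv; b1 <- cfg$block1; b2 <- cfg$block2
  ca <- list()
  c0 <- conv_fwd(x, params$conv0_W, params$conv0_b, cfg$frame_length, B,
                 ic$kernel, ic$stride, 0L)
  n0 <- bn_fwd(c0$out, params$bn0_g, params$bn0_b, state$bn0, training)
  state$bn0 <- n0$state
  r0 <- relu_fwd(n0$out)
  mp <- maxpool_fwd(r0, geom$L1, B, cfg$pool_size)
  p1 <- (b1$kernel - 1L) %/% 2L
  c1 <- conv_fwd(mp$out, params$b1c1_W, params$b1c1_b, geom$L2, B,
                 b1$kernel, 1L, p1)
  n1 <- bn_fwd(c1$out, params$b1bn1_g, params$b1bn1_b, state$b1bn1,
               training)
  state$b1bn1 <- n1$state
  r1 <- relu_fwd(n1$out)
  c2 <- conv_fwd(r1, params$b1c2_W, params$b1c2_b, geom$L2, B, b1$kernel,
                 1L, p1)
  n2 <- bn_fwd(c2$out, params$b1bn2_g, params$b1bn2_b, state$b1bn2,
               training)
  state$b1bn2 <- n2$state
  a1 <- n2$out + mp$out          # identity shortcut
  r2 <- relu_fwd(a1)
  p2 <- (b2$kernel - 1L) %/% 2L
  c3 <- conv_fwd(r2, params$b2c1_W, params$b2c1_b, geom$L2, B, b2$kernel,
                 b2$stride, p2)
  n3 <- bn_fwd(c3$out, params$b2bn1_g, params$b2bn1_b, state$b2bn1,
               training)
  state$b2bn1 <- n3$state
  r3 <- relu_fwd(n3$out)
  c4 <- conv_fwd(r3, params$b2c2_W, params$b2c2_b, geom$L3, B, b2$kernel,
                 1L, p2)
  n4 <- bn_fwd(c4$out, params$b2bn2_g, params$b2bn2_b, state$b2bn2,
               training)
  state$b2bn2 <- n4$state
  sc <- conv_fwd(r2, params$b2sc_W, params$b2sc_b, geom$L2, B, 1L,
                 b2$stride, 0L)
  nsc <- bn_fwd(sc$out, params$b2scbn_g, params$b2scbn_b, state$b2scbn,
                training)
  state$b2scbn <- nsc$state
  a2 <- n4$out + nsc$out         # projection shortcut
  r4 <- relu_fwd(a2)
  gp <- gap_fwd(r4, geom$L3, B)
  list(emb = gp$out, state = state,
       cache = list(c0 = c0, n0 = n0, r0 = r0, mp = mp, c1 = c1, n1 = n1,
                    r1 = r1, c2 = c2, n2 = n2, r2 = r2, c3 = c3, n3 = n3,
                    r3 = r3, c4 = c4, n4 = n4, sc = sc, nsc = nsc,
                    r4 = r4, gp = gp))
}

cnn_backward <- function(demb, cache, params) {
  g <- list()
  dx <- gap_bwd(demb, cache$gp$cache)
  dx <- relu_bwd(dx, cache$r4)
  # projection branch
  bsc <- bn_bwd(dx, cache$nsc$cache)
  g$b2scbn_g <- bsc$dgamma; g$b2scbn_b <- bsc$dbeta
  csc <- conv_bwd(bsc$dx, cache$sc$cache)
  g$b2sc_W <- csc$dW; g$b2sc_b <- csc$db
  # main branch
  b4 <- bn_bwd(dx, cache$n4$cache)
  g$b2bn2_g <- b4$dgamma; g$b2bn2_b <- b4$dbeta
  c4 <- conv_bwd(b4$dx, cache$c4$cache)
  g$b2c2_W <- c4$dW; g$b2c2_b <- c4$db
  dr3 <- relu_bwd(c4$dx, cache$r3)
  b3 <- bn_bwd(dr3, cache$n3$cache)
  g$b2bn1_g <- b3$dgamma; g$b2bn1_b <- b3$dbeta
  c3 <- conv_bwd(b3$dx, cache$c3$cache)
  g$b2c1_W <- c3$dW; g$b2c1_b <- c3$db
  dr2 <- relu_bwd(c3$dx + csc$dx, cache$r2)
  # identity block
  b2g <- bn_bwd(dr2, cache$n2$cache)
  g$b1bn2_g <- b2g$dgamma; g$b1bn2_b <- b2g$dbeta
  c2 <- conv_bwd(b2g$dx, cache$c2$cache)
  g$b1c2_W <- c2$dW; g$b1c2_b <- c2$db
  dr1 <- relu_bwd(c2$dx, cache$r1)
  b1g <- bn_bwd(dr1, cache$n1$cache)
  g$b1bn1_g <- b1g$dgamma; g$b1bn1_b <- b1g$dbeta
  c1 <- conv_bwd(b1g$dx, cache$c1$cache)
  g$b1c1_W <- c1$dW; g$b1c1_b <- c1$db
  dmp <- c1$dx + dr2             # identity shortcut gradient
  dr0 <- maxpool_bwd(dmp, cache$mp$cache)
  dr0 <- relu_bwd(dr0, cache$r0)
  b0 <- bn_bwd(dr0, cache$n0$cache)
  g$bn0_g <- b0$dgamma; g$bn0_b <- b0$dbeta
  c0 <- conv_bwd(b0$dx, cache$c0$cache)
  g$conv0_W <- c0$dW; g$conv0_b <- c0$db
  g
}

model_forward <- function(model, blocks, training = FALSE) {
  cfg <- model$config
  inp <- assemble_input(blocks, cfg)
  cnn <- cnn_forward(inp$x, model$params, model$state, cfg, model$geom,
                     inp$B, training)
  Fn <- cfg$frames; R <- inp$R
  xs <- lapply(seq_len(Fn), function(f)
    cnn$emb[f + (seq_len(R) - 1L) * Fn, , drop = FALSE])
  bl <- bilstm_fwd(xs, model$params, cfg$lstm_units)
  at <- attention_fwd(bl$hs, model$params$att_Wa, model$params$att_ba,
                      model$params$att_va)
  logits <- as.vector(at$context %*% model$params$out_w) +
    model$params$out_b
  probs <- pmin(pmax(sigmoid(logits), 1e-12), 1 - 1e-12)
  list(probs = probs, state = cnn$state,
       cache = list(cnn = cnn, xs = xs, bl = bl, at = at, R = R,
                    context = at$context))
}

model_loss_grads <- function(model, blocks, y, training = TRUE) {
  fwd <- model_forward(model, blocks, training)
  p <- fwd$probs
  R <- fwd$cache$R
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dlogit <- matrix((p - y) / R, R, 1)
  g <- list(out_w = crossprod(fwd$cache$context, dlogit),
            out_b = sum(dlogit))
  dcontext <- dlogit %*% t(model$params$out_w)
  ab <- attention_bwd(dcontext, fwd$cache$at$cache)
  g$att_Wa <- ab$Wa; g$att_ba <- ab$ba; g$att_va <- ab$va
  bb <- bilstm_bwd(ab$dhs, fwd$cache$bl, model$params, model$config$lstm_units)
  g$lstm_f_W <- bb$lstm_f_W; g$lstm_f_b <- bb$lstm_f_b
  g$lstm_b_W <- bb$lstm_b_W; g$lstm_b_b <- bb$lstm_b_b
  Fn <- model$config$frames
  demb <- matrix(0, Fn * R, ncol(fwd$cache$cnn$emb))
  for (f in seq_len(Fn))
    demb[f + (seq_len(R) - 1L) * Fn, ] <- bb$dxs[[f]]
  g <- c(g, cnn_backward(demb, fwd$cache$cnn$cache, model$params))
  list(loss = loss, grads = g, state = fwd$state, probs = p)
}

#' Train a classifier on labeled frame blocks
#'
#' Minimizes binary cross-entropy with Adam over shuffled record
#' minibatches; `config$seed` fixes initialization and shuffling, so two
#' runs with the same data and seed produce identical loss curves. When a
#' validation set is supplied, training stops early after
#' `config$patience` epochs without validation-loss improvement and the
#' best parameters are restored.
#'
#' @param model An untrained (or previously trained) `ecgfb_model`.
#' @param blocks List of `frame_block`s matching the model's input shape.
#' @param labels 0/1 vector, one per block; both classes must be present.
#' @param validation_blocks,validation_labels Optional held-out set for
#'   early stopping.
#' @param verbose Print per-epoch losses?
#' @return The trained model, with `history$train_loss` (and
#'   `history$val_loss`) per epoch.
#' @export
train_model <- function(model, blocks, labels, validation_blocks = NULL,
                        validation_labels = NULL, verbose = FALSE) {
  cfg <- model$config
  y <- as.integer(labels)
  if (length(unique(y)) < 2)
    stop_ecgfb("ecgfb_training_error",
               "training data contains a single class")
  if (length(blocks) != length(y))
    stop_ecgfb("ecgfb_parameter_error", "blocks and labels length mismatch")
  opt <- adam_init(model$params)
  n <- length(blocks)
  train_loss <- numeric(0)
  val_loss <- numeric(0)
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(seed_stream(cfg$seed, paste0("epoch", epoch)),
                     sample(n))
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      lg <- model_loss_grads(model, blocks[idx], y[idx], training = TRUE)
      if (!is.finite(lg$loss))
        stop_ecgfb("ecgfb_divergence_error",
                   "non-finite training loss at epoch %d", epoch)
      model$state <- lg$state
      upd <- adam_step(model$params, lg$grads, opt, cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$opt
      losses <- c(losses, lg$loss)
    }
    train_loss <- c(train_loss, mean(losses))
    gc(FALSE)
    if (!is.null(validation_blocks)) {
      vp <- model_probs(model, validation_blocks)
      vy <- as.integer(validation_labels)
      vl <- -mean(vy * log(vp) + (1 - vy) * log(1 - vp))
      val_loss <- c(val_loss, vl)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        mean(losses), vl))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params,
                     state = model$state, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    } else if (verbose) {
      message(sprintf("epoch %d: train %.4f", epoch, mean(losses)))
    }
  }
  if (!is.null(validation_blocks) && is.finite(best$loss)) {
    model$params <- best$params
    model$state <- best$state
  }
  model$history <- list(train_loss = train_loss,
                        val_loss = if (length(val_loss)) val_loss)
  model$trained <- TRUE
  model
}

# Cache-free inference in record chunks: evaluation-mode batch norm does
# not depend on batch composition, so chunking is exact and keeps the
# forward-pass memory bounded by the chunk size.
model_probs <- function(model, blocks, chunk = model$config$batch_size) {
  n <- length(blocks)
  p <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    p[idx] <- model_forward(model, blocks[idx], training = FALSE)$probs
  }
  p
}

#' Predict class probabilities and calls for frame blocks
#'
#' @param model A trained `ecgfb_model`.
#' @param blocks List of `frame_block`s.
#' @param threshold Decision threshold; defaults to the config's. A
#'   probability equal to the threshold is called positive.
#' @return List with `probabilities` (in (0,1)) and `calls` (0/1).
#' @export
predict_model <- function(model, blocks, threshold = NULL) {
  threshold <- threshold %||% model$config$threshold
  p <- model_probs(model, blocks)
  list(probabilities = p, calls = as.integer(p >= threshold))
}

#' Multi-label prediction by binary relevance
#'
#' A record's predicted label set is the union of the classes whose binary
#' model calls it positive; the empty set is a valid prediction.
#'
#' @param models Named list of trained `ecgfb_model`s, one per class.
#' @param blocks List of `frame_block`s.
#' @param vocabulary Classes that must be covered; a class without a model
#'   is a configuration error.
#' @return List (one element per record) of character label vectors.
#' @export
multilabel_predict <- function(models, blocks,
                               vocabulary = names(models)) {
  missing_cls <- setdiff(vocabulary, names(models))
  if (length(missing_cls))
    stop_ecgfb("ecgfb_configuration_error",
               "no trained model for class(es): %s",
               paste(missing_cls, collapse = ", "))
  calls <- lapply(vocabulary, function(cls)
    predict_model(models[[cls]], blocks)$calls)
  names(calls) <- vocabulary
  lapply(seq_along(blocks), function(i)
    vocabulary[vapply(vocabulary, function(cls) calls[[cls]][i] == 1L,
                      logical(1))])
}
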