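test_that("attention weights are a proper convex combination", {
  # single step: weight exactly 1 and context equals the step
  seq1 <- matrix(c(1.5, -2, 0.5), 1, 3)
  ap1 <- attention_pool(seq1, seed = 1)
  expect_identical(ap1$weights, 1)
  expect_equal(ap1$context, as.vector(seq1))
  for (i in 1:50) {
    s <- ecgfb:::with_seed(i, matrix(stats::rnorm(7 * 6), 7, 6))
    ap <- attention_pool(s, seed = i)
    expect_true(all(ap$weights >= 0))
    expect_equal(sum(ap$weights), 1, tolerance = 1e-6)
    expect_equal(ap$context, as.vector(t(s) %*% ap$weights),
                 tolerance = 1e-9)
  }
  expect_error(attention_pool(matrix(numeric(0), 0, 3)),
               class = "ecgfb_parameter_error")
})

test_that("a dominant attention score concentrates the pooling", {
  # hand-constructed params: v aligned with feature 1, huge margin
  s <- rbind(c(100, 0), c(0, 0), c(-100, 0))
  params <- list(W = diag(2), b = c(0, 0), v = c(10, 0))
  ap <- attention_pool(s, params = params)
  expect_gt(ap$weights[1], 0.999)
  expect_equal(ap$context, s[1, ], tolerance = 1e-2)
})

test_that("forward pass yields probabilities and is deterministic", {
  cfg <- tiny_model_config(seed = 3)
  m <- build_model(cfg)
  blks <- tiny_blocks(4, seed = 10)
  p1 <- predict_model(m, blks, threshold = 0.5)
  p2 <- predict_model(m, blks, threshold = 0.5)
  expect_true(all(p1$probabilities > 0 & p1$probabilities < 1))
  expect_identical(p1$probabilities, p2$probabilities)
  # same seed rebuild -> same parameters -> same outputs
  expect_identical(predict_model(build_model(cfg), blks)$probabilities,
                   p1$probabilities)
  # shape mismatch is a construction error naming both shapes
  wrong <- tiny_blocks(1, seed = 1,
                       cfg = tiny_model_config(frames = 4))
  wrong <- lapply(wrong, function(b) {
    b$data <- b$data[, 1:32, , drop = FALSE]
    b
  })
  expect_error(predict_model(m, wrong), class = "ecgfb_construction_error")
})

test_that("the trunk layer census is 13 by the documented convention", {
  cen <- layer_census(build_model(tiny_model_config()))
  expect_identical(cen$conv, 6L)
  expect_identical(cen$batch_norm, 6L)
  expect_identical(cen$max_pool, 1L)
  expect_identical(cen$total, 13L)
  # the census is architectural, not capacity-dependent
  expect_identical(layer_census(model_config())$total, 13L)
})

test_that("identity residual block reduces to ReLU(input) when zeroed", {
  cfg <- tiny_model_config(seed = 2)
  m <- build_model(cfg)
  # zero the block-1 convolutions, make its batch norms the identity
  for (nm in c("b1c1_W", "b1c1_b", "b1c2_W", "b1c2_b", "b1bn1_b",
               "b1bn2_b"))
    m$params[[nm]] <- m$params[[nm]] * 0
  for (nm in c("b1bn1_g", "b1bn2_g"))
    m$params[[nm]] <- m$params[[nm]] * 0 + 1
  blks <- tiny_blocks(3, seed = 5)
  inp <- ecgfb:::assemble_input(blks, cfg)
  # eval mode with fresh running stats (mean 0, var 1) keeps BN identity
  fwd <- ecgfb:::cnn_forward(inp$x, m$params, m$state, cfg, m$geom, inp$B,
                             training = FALSE)
  mp_out <- fwd$cache$mp$out
  block1_out <- fwd$cache$r2
  expect_equal(block1_out, pmax(mp_out, 0), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- tiny_model_config(seed = 3)
  m <- build_model(cfg)
  blks <- tiny_blocks(5, seed = 20)
  y <- c(1, 0, 1, 0, 1)
  lg <- ecgfb:::model_loss_grads(m, blks, y, training = TRUE)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- ecgfb:::with_seed(nchar(nm) + length(p),
                             sample(length(p), min(2, length(p))))
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm <- m; mm$params[[nm]][i] <- p[i] - eps
      num <- (ecgfb:::model_loss_grads(mp, blks, y, TRUE)$loss -
                ecgfb:::model_loss_grads(mm, blks, y, TRUE)$loss) / (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  cfg <- tiny_model_config(seed = 4, epochs = 10,
                           learning_rate = 3e-3)
  # separable toy task: positives have a large lead-1 offset
  blks <- tiny_blocks(16, seed = 30, cfg = cfg)
  y <- rep(c(1L, 0L), 8)
  for (i in which(y == 1))
    blks[[i]]$data <- blks[[i]]$data + 3
  m1 <- train_model(build_model(cfg), blks, y)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_model(build_model(cfg), blks, y)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params, m2$params)
  expect_error(train_model(build_model(cfg), blks, rep(1L, 16)),
               class = "ecgfb_training_error")
})

test_that("threshold calls are inclusive at the boundary and monotone", {
  cfg <- tiny_model_config(seed = 6, epochs = 2)
  blks <- tiny_blocks(6, seed = 40, cfg = cfg)
  m <- train_model(build_model(cfg), blks, c(1, 0, 1, 0, 1, 0))
  probs <- predict_model(m, blks)$probabilities
  # boundary: threshold equal to an observed probability calls positive
  calls_at <- as.integer(probs >= probs[1])
  expect_identical(predict_model(m, blks,
                                 threshold = probs[1])$calls, calls_at)
  thresholds <- sort(c(1e-6, 0.25, 0.5, 0.75, 1 - 1e-6))
  n_pos <- vapply(thresholds, function(th)
    sum(predict_model(m, blks, threshold = th)$calls), integer(1))
  expect_true(all(diff(n_pos) <= 0))
  expect_identical(n_pos[length(n_pos)], 0L)
})

test_that("multilabel prediction is the union of per-class calls", {
  cfg <- tiny_model_config(seed = 7, epochs = 2)
  blks <- tiny_blocks(4, seed = 50, cfg = cfg)
  y <- c(1, 0, 1, 0)
  m <- train_model(build_model(cfg), blks, y)
  always <- m; always$params$out_b <- 50   # sigmoid ~ 1
  never <- m; never$params$out_b <- -50    # sigmoid ~ 0
  sets <- multilabel_predict(list(AF = always, RBBB = always,
                                  PVC = never), blks)
  for (s in sets) expect_identical(s, c("AF", "RBBB"))
  empty <- multilabel_predict(list(AF = never, RBBB = never), blks)
  for (s in empty) expect_length(s, 0)
  # adding a model never removes predicted labels
  more <- multilabel_predict(list(AF = always, RBBB = always,
                                  PVC = never, STD = always), blks)
  for (i in seq_along(sets))
    expect_true(all(sets[[i]] %in% more[[i]]))
  expect_error(multilabel_predict(list(AF = always), blks,
                                  vocabulary = c("AF", "PVC")),
               class = "ecgfb_configuration_error")
})
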