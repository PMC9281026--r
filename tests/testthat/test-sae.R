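test_that("encode/decode are sigmoid affine maps with range (0,1)", {
  layer <- random_layer(3, 2, seed = 1)
  zero <- list(W = matrix(0, 2, 3), b = rep(0, 2),
               W_dec = matrix(0, 3, 2), b_dec = rep(0, 3))
  x <- matrix(runif(15), 5, 3)
  expect_equal(sae_encode(zero, x), matrix(0.5, 5, 2))
  expect_equal(sae_decode(zero, matrix(runif(10), 5, 2)), matrix(0.5, 5, 3))
  # saturation: large positive bias drives activations toward 1
  sat <- zero; sat$b <- rep(50, 2)
  expect_true(all(sae_encode(sat, x) > 1 - 1e-12))
  h <- sae_encode(layer, x)
  expect_true(all(h > 0 & h < 1))
  expect_true(all(sae_decode(layer, h) > 0 & sae_decode(layer, h) < 1))
  expect_error(sae_encode(layer, matrix(0, 2, 4)), "width")
})

test_that("KL sparsity penalty is a divergence", {
  expect_equal(kl_sparsity(rep(0.05, 7), 0.05), 0)
  # direct evaluation: rho=0.05, rho_hat=0.5
  expect_equal(kl_sparsity(0.5, 0.05),
               0.05 * log(0.1) + 0.95 * log(1.9), tolerance = 1e-12)
  expect_equal(kl_sparsity(0.5, 0.05), 0.4946319, tolerance = 1e-6)
  set.seed(2)
  for (rep in 1:10) {
    rh <- runif(4, 0.01, 0.99)
    expect_gte(kl_sparsity(rh, 0.2), 0)
    if (any(abs(rh - 0.2) > 1e-9)) expect_gt(kl_sparsity(rh, 0.2), 0)
  }
  expect_error(kl_sparsity(c(0.2, 1), 0.1), "boundary")
  expect_error(kl_sparsity(0, 0.1), "boundary")
})

test_that("the sparse layer loss reduces to its parts in ablation", {
  layer <- random_layer(4, 3, seed = 3)
  x <- matrix(runif(20), 5, 4)
  # lambda = beta = 0 -> pure half mean squared reconstruction error
  xhat <- sae_decode(layer, sae_encode(layer, x))
  expect_equal(sparse_ae_loss(layer, x, 0, 0, 0.05),
               mean(0.5 * rowSums((xhat - x)^2)), tolerance = 1e-12)
  # all-zero parameters, batch at 0.5, rho = 0.5: every term vanishes
  zero <- list(W = matrix(0, 3, 4), b = rep(0, 3),
               W_dec = matrix(0, 4, 3), b_dec = rep(0, 4))
  expect_equal(sparse_ae_loss(zero, matrix(0.5, 6, 4), 0.1, 0.7, 0.5), 0,
               tolerance = 1e-12)
  # beta > 0 can only increase the loss when rho_hat != rho
  expect_gte(sparse_ae_loss(layer, x, 1e-3, 0.5, 0.05),
             sparse_ae_loss(layer, x, 1e-3, 0, 0.05))
})

test_that("analytic layer gradients match central finite differences", {
  n_in <- 4; n_hidden <- 3
  layer <- random_layer(n_in, n_hidden, seed = 4)
  set.seed(5)
  x <- matrix(runif(5 * n_in), 5, n_in)
  lambda <- 1e-3; beta <- 0.3; rho <- 0.1
  g <- crowsae:::sparse_ae_grad(layer, x, lambda, beta, rho)
  analytic <- pack_layer(g)
  numeric <- numeric_gradient(function(theta) {
    sparse_ae_loss(unpack_layer(theta, n_in, n_hidden), x, lambda, beta, rho)
  }, pack_layer(layer))
  expect_lt(max_rel_err(analytic, numeric), 1e-5)
})

test_that("pretraining descends the loss and respects a zero step size", {
  d <- two_cluster_dataset(n = 40, d = 5, seed = 6)
  x <- d$features
  x <- sweep(sweep(x, 2, apply(x, 2, min)), 2,
             apply(x, 2, max) - apply(x, 2, min), "/")
  ctl <- sae_control(hidden_sizes = 3, pretrain_epochs = 20,
                     learning_rate = 0.5, batch_size = 10, seed = 1)
  set.seed(1)
  layer <- pretrain_layer(x, 3, ctl)
  hist <- attr(layer, "loss_history")
  expect_length(hist, 21)
  expect_lt(hist[length(hist)], hist[1])

  # zero learning rate leaves parameters untouched
  ctl0 <- sae_control(hidden_sizes = 3, pretrain_epochs = 5, learning_rate = 0)
  set.seed(2)
  frozen <- pretrain_layer(x, 3, ctl0)
  h0 <- attr(frozen, "loss_history")
  expect_true(all(abs(h0 - h0[1]) < 1e-12))

  # duplicated columns compress: reconstruction error under the input variance
  set.seed(3)
  base <- matrix(runif(60), 30, 2)
  dup <- cbind(base, base, base)     # 6 columns, rank 2
  ctl2 <- sae_control(hidden_sizes = 2, pretrain_epochs = 200,
                      learning_rate = 1, sparsity_weight = 0,
                      weight_decay = 0, batch_size = 30)
  set.seed(4)
  trained <- pretrain_layer(dup, 2, ctl2)
  recon <- sae_decode(trained, sae_encode(trained, dup))
  expect_lt(mean((recon - dup)^2), mean(apply(dup, 2, var)))
})

test_that("fine-tune cost matches closed forms and its gradient checks out", {
  # uniform two-class predictor costs ln 2
  layers <- list(random_layer(3, 2, seed = 7))
  model <- crowsae:::new_sae_model(layers,
                                   list(W = matrix(0, 2, 2), b = c(0, 0)), 2)
  set.seed(8)
  x <- matrix(runif(12), 4, 3)
  y <- c(0L, 1L, 0L, 1L)
  expect_equal(finetune_cost(model, x, y), log(2), tolerance = 1e-12)

  # near-certain correct predictions cost ~0
  sure <- model
  sure$layers <- list(list(W = matrix(0, 2, 3), b = c(50, -50),
                           W_dec = matrix(0, 3, 2), b_dec = rep(0, 3)))
  sure$softmax <- list(W = matrix(c(100, -100, -100, 100), 2, 2), b = c(0, 0))
  h <- crowsae:::sae_forward(sure$layers, x)[[1]]
  pred <- max.col(h %*% t(sure$softmax$W))
  expect_lt(finetune_cost(sure, x, pred - 1L), 1e-6)

  expect_error(finetune_cost(model, x, c(0L, 2L, 0L, 1L)), "range")

  # gradient of the whole-network cost vs finite differences
  model2 <- crowsae:::new_sae_model(
    list(random_layer(4, 3, seed = 9), random_layer(3, 2, seed = 10)),
    list(W = matrix(rnorm(4, sd = 0.5), 2, 2), b = rnorm(2, sd = 0.1)), 2)
  set.seed(11)
  xb <- matrix(runif(20), 5, 4)
  yb <- c(0L, 1L, 1L, 0L, 1L)
  g <- crowsae:::finetune_grad(model2, xb, yb)
  pack_model <- function(m) {
    c(unlist(lapply(m$layers, function(l) c(l$W, l$b))),
      m$softmax$W, m$softmax$b)
  }
  pack_grad <- c(unlist(lapply(g$layers, function(l) c(l$W, l$b))),
                 g$softmax$W, g$softmax$b)
  shapes <- list(c(3, 4), c(2, 3))
  unpack_model <- function(theta) {
    m <- model2; i <- 0
    take <- function(n) { out <- theta[(i + 1):(i + n)]; i <<- i + n; out }
    for (l in 1:2) {
      m$layers[[l]]$W <- matrix(take(prod(shapes[[l]])), shapes[[l]][1],
                                shapes[[l]][2])
      m$layers[[l]]$b <- take(shapes[[l]][1])
    }
    m$softmax$W <- matrix(take(4), 2, 2)
    m$softmax$b <- take(2)
    m
  }
  numeric <- numeric_gradient(function(theta) {
    finetune_cost(unpack_model(theta), xb, yb)
  }, pack_model(model2))
  expect_lt(max_rel_err(pack_grad, numeric), 1e-5)
})

test_that("fine-tuning learns a separable problem and is an identity at zero epochs", {
  d <- two_cluster_dataset(n = 60, d = 2, gap = 4, seed = 12)
  ctl <- sae_control(hidden_sizes = 4, pretrain_epochs = 10,
                     finetune_epochs = 80, learning_rate = 1, batch_size = 20,
                     seed = 3)
  fit <- sae(d, control = ctl)
  hist <- fit$history$finetune
  expect_lt(hist[length(hist)], hist[1])
  expect_equal(mean(predict(fit, d$features) == d$labels), 1)

  ctl0 <- sae_control(hidden_sizes = 4, pretrain_epochs = 5,
                      finetune_epochs = 0, seed = 3)
  f0 <- sae(d, control = ctl0)
  f0b <- sae(d, control = ctl0)
  expect_identical(f0$layers, f0b$layers)  # no fine-tune randomness consumed
  expect_length(f0$history$finetune, 1)
})

test_that("predictions are proper probabilities, shift-invariant, ties to class 0", {
  d <- two_cluster_dataset(n = 40, d = 3, seed = 13)
  fit <- sae(d, control = sae_control(hidden_sizes = 3, pretrain_epochs = 3,
                                      finetune_epochs = 3, seed = 5))
  p <- predict(fit, d$features, type = "prob")
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-9)
  # adding a constant to every class logit leaves probabilities unchanged
  shifted <- fit
  shifted$softmax$b <- shifted$softmax$b + 123.4
  expect_equal(predict(shifted, d$features, type = "prob"), p,
               tolerance = 1e-9)
  # zero head: uniform probabilities, hard labels all the lower class
  flat <- fit
  flat$softmax$W[] <- 0; flat$softmax$b[] <- 0
  pf <- predict(flat, d$features, type = "prob")
  expect_true(all(abs(pf - 0.5) < 1e-12))
  expect_true(all(predict(flat, d$features) == 0))
})

test_that("training is bit-reproducible from the seed", {
  d <- two_cluster_dataset(n = 30, d = 3, seed = 14)
  ctl <- sae_control(hidden_sizes = c(4, 2), pretrain_epochs = 4,
                     finetune_epochs = 4, seed = 99)
  m1 <- sae(d, control = ctl)
  m2 <- sae(d, control = ctl)
  expect_identical(m1, m2)
})

test_that("formula and dataset interfaces agree with the matrix interface", {
  d <- two_cluster_dataset(n = 30, d = 2, seed = 15)
  df <- data.frame(d$features, pph = d$labels)
  ctl <- sae_control(hidden_sizes = 2, pretrain_epochs = 2,
                     finetune_epochs = 2, seed = 1)
  m_mat <- sae(d$features, d$labels, control = ctl)
  m_ds <- sae(d, control = ctl)
  m_f <- sae(pph ~ ., data = df, control = ctl)
  expect_equal(m_mat$softmax, m_ds$softmax)
  expect_equal(m_mat$softmax, m_f$softmax, ignore_attr = TRUE)
})
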