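#' Training control for the sparse stacked autoencoder
#'
#' Collects the hyperparameters of the classifier in one validated list.
#' These are exactly the quantities the equilibrium-optimizer tuner can
#' search over (see [tune_sae()]).
#'
#' @param hidden_sizes Integer vector of hidden-layer widths, one per
#'   stacked autoencoder. Default `c(16, 8)`.
#' @param weight_decay Weight-attenuation coefficient (lambda) of the
#'   squared-norm penalty. Default `1e-4`.
#' @param sparsity_weight Weight (beta) of the KL sparsity penalty.
#'   Default 0.1.
#' @param sparsity_target Target mean activation (rho) of each hidden
#'   unit, in (0,1). Default 0.05.
#' @param learning_rate Gradient-descent step size. Default 0.5.
#' @param pretrain_epochs Epochs of layer-wise pretraining. Default 30.
#' @param finetune_epochs Epochs of whole-network fine-tuning. Default 30.
#' @param batch_size Mini-batch size; `Inf` trains full-batch. Default 32.
#' @param init_scale Half-width of the symmetric-uniform weight
#'   initialization; `NULL` uses `sqrt(6 / (fan_in + fan_out))` per layer.
#' @param seed Integer seed; training is bit-reproducible from it.
#' @return A list of class `sae_control`.
#' @export
sae_control <- function(hidden_sizes = c(16, 8), weight_decay = 1e-4,
                        sparsity_weight = 0.1, sparsity_target = 0.05,
                        learning_rate = 0.5, pretrain_epochs = 30,
                        finetune_epochs = 30, batch_size = 32,
                        init_scale = NULL, seed = 1) {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            weight_decay >= 0, sparsity_weight >= 0,
            sparsity_target > 0, sparsity_target < 1,
            learning_rate >= 0, pretrain_epochs >= 0, finetune_epochs >= 0,
            batch_size >= 1)
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), weight_decay = weight_decay,
         sparsity_weight = sparsity_weight, sparsity_target = sparsity_target,
         learning_rate = learning_rate,
         pretrain_epochs = as.integer(pretrain_epochs),
         finetune_epochs = as.integer(finetune_epochs),
         batch_size = batch_size, init_scale = init_scale,
         seed = as.integer(seed)),
    class = "sae_control"
  )
}

new_sae_layer <- function(W, b, W_dec, b_dec) {
  stopifnot(nrow(W) == length(b), nrow(W_dec) == length(b_dec),
            ncol(W) == nrow(W_dec), nrow(W) == ncol(W_dec),
            all(is.finite(W)), all(is.finite(W_dec)))
  list(W = W, b = b, W_dec = W_dec, b_dec = b_dec)
}

init_sae_layer <- function(n_in, n_hidden, init_scale = NULL) {
  r_enc <- if (is.null(init_scale)) sqrt(6 / (n_in + n_hidden)) else init_scale
  W <- matrix(stats::runif(n_hidden * n_in, -r_enc, r_enc), n_hidden, n_in)
  W_dec <- matrix(stats::runif(n_in * n_hidden, -r_enc, r_enc), n_in, n_hidden)
  new_sae_layer(W, numeric(n_hidden), W_dec, numeric(n_in))
}

#' Encode a batch through one autoencoder layer
#'
#' `h = sigma(W x + b)` with the logistic sigmoid, applied row-wise to a
#' samples-by-features matrix; all activations lie in (0,1).
#'
#' @param layer A layer as returned by [pretrain_layer()] (fields `W`
#'   hidden-by-input, `b`, `W_dec` input-by-hidden, `b_dec`).
#' @param x Numeric matrix, samples in rows, width equal to `ncol(layer$W)`.
#' @return Activation matrix, samples by hidden units.
#' @export
sae_encode <- function(layer, x) {
  x <- rbind(x)
  if (ncol(x) != ncol(layer$W)) stop("input width mismatch", call. = FALSE)
  sigmoid(sweep(x %*% t(layer$W), 2, layer$b, "+"))
}

#' Decode hidden activations through one autoencoder layer
#'
#' `xhat = sigma(W' h + b')`; the reconstruction lives in (0,1), which is
#' why inputs are min-max scaled before training.
#'
#' @param layer A layer (see [sae_encode()]).
#' @param h Activation matrix, samples by hidden units.
#' @return Reconstruction matrix, samples by inputs.
#' @export
sae_decode <- function(layer, h) {
  h <- rbind(h)
  if (ncol(h) != ncol(layer$W_dec)) stop("hidden width mismatch", call. = FALSE)
  sigmoid(sweep(h %*% t(layer$W_dec), 2, layer$b_dec, "+"))
}

#' KL divergence sparsity penalty
#'
#' `sum_j [ rho*ln(rho/rho_hat_j) + (1-rho)*ln((1-rho)/(1-rho_hat_j)) ]`
#' (natural logs): the Kullback-Leibler divergence between the target
#' activation rate and each hidden unit's observed mean activation, summed
#' over units. Non-negative, zero iff every `rho_hat_j == rho`.
#'
#' @param rho_hat Mean activations, strictly inside (0,1). Boundary values
#'   are an error — upstream code must decide how to clip, not this
#'   function.
#' @param rho Target activation rate in (0,1).
#' @return Scalar penalty `>= 0`.
#' @examples
#' kl_sparsity(c(0.05, 0.05), 0.05)  # 0
#' kl_sparsity(0.5, 0.05)
#' @export
kl_sparsity <- function(rho_hat, rho) {
  stopifnot_scalar_prob(rho, "rho")
  if (any(rho_hat <= 0 | rho_hat >= 1)) {
    stop("`rho_hat` has entries on the boundary of (0,1); clip explicitly upstream",
         call. = FALSE)
  }
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

#' Sparse autoencoder loss for one layer
#'
#' Composite training objective of one layer on a batch:
#' `mean_i 0.5 * ||xhat_i - x_i||^2  +  (lambda/2) * (||W||_F^2 + ||W'||_F^2)
#'  +  beta * KL(rho_hat || rho)`,
#' with `rho_hat_j` the batch-mean activation of hidden unit `j`. Batch
#' means of exactly 0 or 1 are clipped to `[1e-6, 1 - 1e-6]` with a
#' warning before the KL term.
#'
#' @param layer A layer (see [sae_encode()]).
#' @param batch Numeric matrix of inputs, samples in rows, non-empty.
#' @param weight_decay,sparsity_weight,sparsity_target The lambda, beta and
#'   rho of [sae_control()].
#' @return Scalar loss.
#' @export
sparse_ae_loss <- function(layer, batch, weight_decay = 1e-4,
                           sparsity_weight = 0.1, sparsity_target = 0.05) {
  batch <- rbind(batch)
  if (nrow(batch) == 0L) stop("empty batch", call. = FALSE)
  h <- sae_encode(layer, batch)
  xhat <- sae_decode(layer, h)
  recon <- mean(0.5 * rowSums((xhat - batch)^2))
  decay <- weight_decay / 2 * (sum(layer$W^2) + sum(layer$W_dec^2))
  sparse <- 0
  if (sparsity_weight > 0) {
    rho_hat <- colMeans(h)
    if (any(rho_hat <= 1e-6 | rho_hat >= 1 - 1e-6)) {
      warning("batch-mean activation at the (0,1) boundary; clipping for the KL term")
      rho_hat <- pmin(1 - 1e-6, pmax(1e-6, rho_hat))
    }
    sparse <- sparsity_weight * kl_sparsity(rho_hat, sparsity_target)
  }
  recon + decay + sparse
}

# Analytic gradient of sparse_ae_loss wrt all four parameter blocks.
sparse_ae_grad <- function(layer, batch, weight_decay, sparsity_weight,
                           sparsity_target) {
  batch <- rbind(batch)
  n <- nrow(batch)
  h <- sae_encode(layer, batch)
  xhat <- sae_decode(layer, h)
  delta_out <- (xhat - batch) * xhat * (1 - xhat) / n
  gW_dec <- t(delta_out) %*% h + weight_decay * layer$W_dec
  gb_dec <- colSums(delta_out)
  back <- delta_out %*% layer$W_dec
  if (sparsity_weight > 0) {
    rho_hat <- pmin(1 - 1e-6, pmax(1e-6, colMeans(h)))
    kl_d <- sparsity_weight *
      (-sparsity_target / rho_hat + (1 - sparsity_target) / (1 - rho_hat)) / n
    back <- sweep(back, 2, kl_d, "+")
  }
  delta_h <- back * h * (1 - h)
  list(W = t(delta_h) %*% batch + weight_decay * layer$W,
       b = colSums(delta_h),
       W_dec = gW_dec,
       b_dec = gb_dec)
}

#' Pretrain one sparse autoencoder layer
#'
#' Initializes encoder and decoder weights from symmetric-uniform draws
#' (biases at zero) and runs mini-batch gradient descent on
#' [sparse_ae_loss()] for `pretrain_epochs` epochs, reshuffling sample
#' order each epoch.
#'
#' @param x Input matrix, samples in rows (already scaled to `[0,1]` when
#'   called from [sae()]).
#' @param hidden_size Width of the bottleneck, `>= 1`.
#' @param control A [sae_control()].
#' @return The trained layer, with attribute `"loss_history"` holding the
#'   full-data loss after each epoch (entry 0 = at initialization).
#'   Training that produces a non-finite loss aborts with the offending
#'   epoch in the error message.
#' @export
pretrain_layer <- function(x, hidden_size, control = sae_control()) {
  x <- rbind(x)
  stopifnot(hidden_size >= 1, nrow(x) >= 1)
  layer <- init_sae_layer(ncol(x), hidden_size, control$init_scale)
  history <- numeric(control$pretrain_epochs + 1L)
  history[1] <- sparse_ae_loss(layer, x, control$weight_decay,
                               control$sparsity_weight, control$sparsity_target)
  n <- nrow(x)
  bs <- min(control$batch_size, n)
  lr <- control$learning_rate
  for (epoch in seq_len(control$pretrain_epochs)) {
    ord <- sample.int(n)
    before <- layer
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      g <- sparse_ae_grad(layer, x[idx, , drop = FALSE], control$weight_decay,
                          control$sparsity_weight, control$sparsity_target)
      layer$W <- layer$W - lr * g$W
      layer$b <- layer$b - lr * g$b
      layer$W_dec <- layer$W_dec - lr * g$W_dec
      layer$b_dec <- layer$b_dec - lr * g$b_dec
    }
    history[epoch + 1L] <- sparse_ae_loss(layer, x, control$weight_decay,
                                          control$sparsity_weight,
                                          control$sparsity_target)
    if (!is.finite(history[epoch + 1L])) {
      stop(sprintf("pretraining diverged at epoch %d", epoch), call. = FALSE)
    }
    # step-size safeguard: a clearly rising full-data loss means the fixed
    # step overshot — revert the epoch and halve the step (small fluctuations
    # from mini-batch noise are left alone)
    if (history[epoch + 1L] > history[epoch] * (1 + 1e-2)) {
      layer <- before
      history[epoch + 1L] <- history[epoch]
      lr <- lr / 2
    }
  }
  attr(layer, "loss_history") <- history
  layer
}

# Forward pass through the encoder stack; returns list of activations per
# layer (last element = final hidden representation).
sae_forward <- function(layers, x) {
  acts <- vector("list", length(layers))
  h <- rbind(x)
  for (l in seq_along(layers)) {
    h <- sae_encode(layers[[l]], h)
    acts[[l]] <- h
  }
  acts
}

softmax_probs <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Fine-tuning cost of the stacked network
#'
#' Multinomial cross-entropy of the softmax head over the final hidden
#' representation:
#' `-(1/m) sum_i sum_j 1{y_i = j} * ln softmax_j(theta h_i)`,
#' evaluated with a log-sum-exp for numerical safety. A uniform predictor
#' over two classes costs `ln 2`.
#'
#' @param model A fitted [sae()] model (or the internal stack+head list).
#' @param x Feature matrix on the model's input scale (a fitted model's
#'   stored min-max scaling is applied automatically).
#' @param y Integer class indices in `0 .. n_classes - 1`.
#' @return Scalar cost `>= 0`.
#' @export
finetune_cost <- function(model, x, y) {
  x <- scale_like(model, rbind(x))
  if (any(y < 0 | y >= model$n_classes)) {
    stop("labels out of range 0..n_classes-1", call. = FALSE)
  }
  h <- sae_forward(model$layers, x)
  h_last <- h[[length(h)]]
  logits <- sweep(h_last %*% t(model$softmax$W), 2, model$softmax$b, "+")
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_along(y), y + 1L)]
  mean(lse - picked)
}

# Gradient of the cross-entropy wrt softmax head and all encoder layers
# (decoders frozen). x already scaled.
finetune_grad <- function(model, x, y) {
  n <- nrow(x)
  acts <- sae_forward(model$layers, x)
  h_last <- acts[[length(acts)]]
  logits <- sweep(h_last %*% t(model$softmax$W), 2, model$softmax$b, "+")
  probs <- softmax_probs(logits)
  ind <- matrix(0, n, model$n_classes)
  ind[cbind(seq_len(n), y + 1L)] <- 1
  delta <- (probs - ind) / n
  gWs <- t(delta) %*% h_last
  gbs <- colSums(delta)
  back <- delta %*% model$softmax$W
  g_layers <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    h_l <- acts[[l]]
    delta_l <- back * h_l * (1 - h_l)
    below <- if (l == 1L) x else acts[[l - 1L]]
    g_layers[[l]] <- list(W = t(delta_l) %*% below, b = colSums(delta_l))
    back <- delta_l %*% model$layers[[l]]$W
  }
  list(softmax = list(W = gWs, b = gbs), layers = g_layers)
}

scale_like <- function(model, x) {
  if (is.null(model$scaling)) return(x)
  sweep(sweep(x, 2, model$scaling$min), 2, model$scaling$range, "/")
}

new_sae_model <- function(layers, softmax, n_classes, classes = NULL,
                          scaling = NULL) {
  structure(
    list(layers = layers, softmax = softmax, n_classes = n_classes,
         classes = classes %||% (seq_len(n_classes) - 1L), scaling = scaling),
    class = "sae"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fine-tune a stacked model by backpropagation
#'
#' Mini-batch gradient descent on [finetune_cost()] through the softmax
#' head and every encoder layer; decoder weights stay frozen at their
#' pretrained values. With `finetune_epochs = 0` the model is returned
#' unchanged.
#'
#' @param model A stacked model with softmax head.
#' @param x Feature matrix on the model's input scale.
#' @param y Integer class indices in `0 .. n_classes - 1`.
#' @param control A [sae_control()] (uses `learning_rate`, `batch_size`,
#'   `finetune_epochs`).
#' @return The updated model with attribute `"cost_history"` (full-data
#'   cost after each epoch; entry 0 = before fine-tuning).
#' @export
finetune <- function(model, x, y, control = sae_control()) {
  x_scaled <- scale_like(model, rbind(x))
  n <- nrow(x_scaled)
  bs <- min(control$batch_size, n)
  lr <- control$learning_rate
  unscaled <- model
  unscaled$scaling <- NULL    # cost/grad below work on pre-scaled x
  history <- numeric(control$finetune_epochs + 1L)
  history[1] <- finetune_cost(unscaled, x_scaled, y)
  for (epoch in seq_len(control$finetune_epochs)) {
    ord <- sample.int(n)
    before <- unscaled
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      g <- finetune_grad(unscaled, x_scaled[idx, , drop = FALSE], y[idx])
      unscaled$softmax$W <- unscaled$softmax$W - lr * g$softmax$W
      unscaled$softmax$b <- unscaled$softmax$b - lr * g$softmax$b
      for (l in seq_along(unscaled$layers)) {
        unscaled$layers[[l]]$W <- unscaled$layers[[l]]$W - lr * g$layers[[l]]$W
        unscaled$layers[[l]]$b <- unscaled$layers[[l]]$b - lr * g$layers[[l]]$b
      }
    }
    history[epoch + 1L] <- finetune_cost(unscaled, x_scaled, y)
    if (!is.finite(history[epoch + 1L])) {
      stop(sprintf("fine-tuning diverged at epoch %d", epoch), call. = FALSE)
    }
    # step-size safeguard, as in pretraining: revert and halve on a clear rise
    if (history[epoch + 1L] > history[epoch] * (1 + 1e-2)) {
      unscaled <- before
      history[epoch + 1L] <- history[epoch]
      lr <- lr / 2
    }
  }
  model$layers <- unscaled$layers
  model$softmax <- unscaled$softmax
  attr(model, "cost_history") <- history
  model
}

#' Sparse stacked autoencoder classifier
#'
#' Fits the full classifier: inputs are min-max scaled to `[0,1]` (sigmoid
#' reconstruction targets must be bounded), each hidden layer is pretrained
#' greedily as a sparse autoencoder on the previous layer's code
#' ([pretrain_layer()]), a softmax head is attached to the last hidden
#' layer, and the encoder stack plus head are fine-tuned end-to-end by
#' backpropagation on the cross-entropy ([finetune()]).
#'
#' @param x Numeric feature matrix (samples in rows), a [pph_dataset()],
#'   or a formula.
#' @param y Binary (or small-integer) class labels; ignored when `x` is a
#'   dataset or formula.
#' @param control A [sae_control()] with all hyperparameters.
#' @param data Data frame, when `x` is a formula.
#' @param ... Passed on between methods.
#' @return An object of class `sae` with elements `layers`, `softmax`,
#'   `n_classes`, `classes`, `scaling`, `control` and `history` (per-layer
#'   pretraining losses and the fine-tuning cost curve).
#' @examples
#' s <- synth_pph(150, 6, 2, prevalence = 0.4, seed = 5)
#' fit <- sae(s$dataset, control = sae_control(hidden_sizes = 4,
#'   pretrain_epochs = 5, finetune_epochs = 5, seed = 1))
#' table(predict(fit, s$dataset$features), s$dataset$labels)
#' @export
sae <- function(x, ...) UseMethod("sae")

#' @rdname sae
#' @export
sae.formula <- function(x, data, control = sae_control(), ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(attr(mf, "terms"), mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  sae.default(xm, y, control = control, ...)
}

#' @rdname sae
#' @export
sae.pph_dataset <- function(x, control = sae_control(), ...) {
  sae.default(x$features, x$labels, control = control, ...)
}

#' @rdname sae
#' @export
sae.default <- function(x, y, control = sae_control(), ...) {
  x <- as.matrix(x)
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  y_idx <- match(as.integer(y), classes) - 1L
  n_classes <- length(classes)

  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  ranges[ranges == 0] <- 1
  scaling <- list(min = mins, range = ranges)
  x_scaled <- sweep(sweep(x, 2, mins), 2, ranges, "/")

  with_seed(control$seed, {
    layers <- vector("list", length(control$hidden_sizes))
    pre_hist <- vector("list", length(control$hidden_sizes))
    rep_in <- x_scaled
    for (l in seq_along(control$hidden_sizes)) {
      layers[[l]] <- pretrain_layer(rep_in, control$hidden_sizes[l], control)
      pre_hist[[l]] <- attr(layers[[l]], "loss_history")
      attr(layers[[l]], "loss_history") <- NULL
      rep_in <- sae_encode(layers[[l]], rep_in)
    }
    h_last <- ncol(rep_in)
    r <- control$init_scale %||% sqrt(6 / (h_last + n_classes))
    softmax <- list(
      W = matrix(stats::runif(n_classes * h_last, -r, r), n_classes, h_last),
      b = numeric(n_classes)
    )
    model <- new_sae_model(layers, softmax, n_classes, classes, scaling)
    model <- finetune(model, x, y_idx, control)
    model$control <- control
    model$history <- list(pretrain = pre_hist,
                          finetune = attr(model, "cost_history"))
    attr(model, "cost_history") <- NULL
    model
  })
}

#' Predict method for sparse stacked autoencoder fits
#'
#' @param object A fitted [sae()] model.
#' @param newdata Feature matrix (samples in rows) or a [pph_dataset()].
#' @param type `"class"` for hard labels (argmax, ties toward the lower
#'   class index) or `"prob"` for the class-probability matrix (rows sum
#'   to 1).
#' @param ... Unused.
#' @return Vector of class labels, or a probability matrix with one column
#'   per class.
#' @export
predict.sae <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "pph_dataset")) newdata <- newdata$features
  x <- scale_like(object, rbind(newdata))
  h <- sae_forward(object$layers, x)
  logits <- sweep(h[[length(h)]] %*% t(object$softmax$W), 2,
                  object$softmax$b, "+")
  probs <- softmax_probs(logits)
  colnames(probs) <- as.character(object$classes)
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.sae <- function(x, ...) {
  widths <- vapply(x$layers, function(l) nrow(l$W), integer(1))
  cat(sprintf("<sae> input %d -> [%s] -> softmax(%d classes)\n",
              ncol(x$layers[[1]]$W), paste(widths, collapse = ", "),
              x$n_classes))
  if (!is.null(x$history)) {
    ft <- x$history$finetune
    cat(sprintf("  fine-tune cost %.4f -> %.4f over %d epochs\n",
                ft[1], ft[length(ft)], length(ft) - 1L))
  }
  invisible(x)
}

#' @export
summary.sae <- function(object, ...) {
  n_par <- sum(vapply(object$layers, function(l) {
    length(l$W) + length(l$b) + length(l$W_dec) + length(l$b_dec)
  }, numeric(1))) + length(object$softmax$W) + length(object$softmax$b)
  cat("Sparse stacked autoencoder classifier\n")
  print(object)
  cat(sprintf("  parameters: %d (decoders frozen after pretraining)\n", n_par))
  if (!is.null(object$control)) {
    ctl <- object$control
    cat(sprintf("  lambda=%.2g beta=%.2g rho=%.2g lr=%.2g batch=%s\n",
                ctl$weight_decay, ctl$sparsity_weight, ctl$sparsity_target,
                ctl$learning_rate, format(ctl$batch_size)))
  }
  invisible(object)
}

#' @export
plot.sae <- function(x, ...) {
  ft <- x$history$finetune
  plot(seq_along(ft) - 1L, ft, type = "l", xlab = "fine-tune epoch",
       ylab = "cross-entropy cost", ...)
  invisible(x)
}

#' @export
coef.sae <- function(object, ...) {
  list(softmax_weights = object$softmax$W, softmax_bias = object$softmax$b)
}
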