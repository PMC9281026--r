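# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Central finite differences of a scalar function of a numeric vector.
numeric_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + h
    dn <- x; dn[i] <- dn[i] - h
    g[i] <- (f(up) - f(dn)) / (2 * h)
  }
  g
}

max_rel_err <- function(analytic, numeric) {
  max(abs(analytic - numeric) / pmax(1, abs(numeric)))
}

# Random small autoencoder layer (encoder hidden x input, decoder transposed
# shape), entries well inside the sigmoid's responsive range.
random_layer <- function(n_in, n_hidden, seed = 1) {
  set.seed(seed)
  list(W = matrix(rnorm(n_hidden * n_in, sd = 0.5), n_hidden, n_in),
       b = rnorm(n_hidden, sd = 0.1),
       W_dec = matrix(rnorm(n_in * n_hidden, sd = 0.5), n_in, n_hidden),
       b_dec = rnorm(n_in, sd = 0.1))
}

# Pack/unpack a layer's four parameter blocks into one vector, for
# finite-difference sweeps over all parameters at once.
pack_layer <- function(layer) {
  c(layer$W, layer$b, layer$W_dec, layer$b_dec)
}
unpack_layer <- function(theta, n_in, n_hidden) {
  i <- 0
  take <- function(n) { out <- theta[(i + 1):(i + n)]; i <<- i + n; out }
  list(W = matrix(take(n_hidden * n_in), n_hidden, n_in),
       b = take(n_hidden),
       W_dec = matrix(take(n_in * n_hidden), n_in, n_hidden),
       b_dec = take(n_in))
}

# A deterministic subset-accuracy oracle for wrapper-search tests: accuracy
# rises with planted-feature coverage and falls slowly with noise features,
# so the optimum over masks is known by construction.
planted_evaluator <- function(informative, gain = 0.45, penalty = 0.03) {
  force(informative)
  function(dataset, mask) {
    mask <- as.logical(mask)
    k_inf <- sum(which(mask) %in% informative)
    k_noise <- sum(mask) - k_inf
    min(1, max(0, 0.5 + gain * k_inf / length(informative) - penalty * k_noise))
  }
}

# Exhaustive wrapper-cost minimum over all non-empty masks of d features.
exhaustive_best_cost <- function(d, dataset, evaluator, subset_weight) {
  best <- Inf
  for (code in seq_len(2^d - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(d) - 1)) > 0)
    cost <- fs_cost(mask, dataset, evaluator, subset_weight)
    if (cost < best) best <- cost
  }
  best
}

# Tiny two-cluster dataset, perfectly separable, for classifier checks.
two_cluster_dataset <- function(n = 60, d = 2, gap = 6, seed = 1) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * d, sd = 0.5), n, d) + gap * lab
  pph_dataset(x, lab)
}
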