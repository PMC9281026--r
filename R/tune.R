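#' Hyperparameter search space for the autoencoder classifier
#'
#' Defines the box the equilibrium optimizer searches over, one named
#' dimension per tunable field of [sae_control()]. Dimensions spanning
#' decades (`learning_rate`, `weight_decay`, `sparsity_weight`) are searched
#' on a log10 scale; widths and batch sizes are rounded to integers on
#' decoding, so `decode(encode(config))` reproduces a config up to that
#' rounding.
#'
#' @param ... Named dimensions, each a list with `lower`, `upper`, and
#'   optionally `scale` (`"linear"` or `"log"`, default linear) and `round`
#'   (logical, default `FALSE`). Names must be [sae_control()] fields;
#'   `hidden1`, `hidden2`, ... address individual layer widths.
#' @return A list of class `sae_space` with `names`, `lower`, `upper`
#'   (on the internal search scale) and the per-dimension decode rules.
#' @examples
#' sp <- sae_space(learning_rate = list(lower = 1e-3, upper = 1, scale = "log"),
#'                 sparsity_target = list(lower = 0.02, upper = 0.5),
#'                 hidden1 = list(lower = 4, upper = 32, round = TRUE))
#' decode_sae_point(sp$lower, sp, sae_control())
#' @export
sae_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L) {
    dims <- list(
      learning_rate = list(lower = 1e-2, upper = 1, scale = "log"),
      weight_decay = list(lower = 1e-6, upper = 1e-2, scale = "log"),
      sparsity_weight = list(lower = 1e-3, upper = 1, scale = "log"),
      sparsity_target = list(lower = 0.02, upper = 0.5),
      hidden1 = list(lower = 4, upper = 32, round = TRUE)
    )
  }
  if (is.null(names(dims)) || any(names(dims) == "")) {
    stop("every search dimension must be named", call. = FALSE)
  }
  scale <- vapply(dims, function(d) d$scale %||% "linear", character(1))
  rnd <- vapply(dims, function(d) isTRUE(d$round), logical(1))
  lo <- vapply(dims, function(d) d$lower, numeric(1))
  hi <- vapply(dims, function(d) d$upper, numeric(1))
  stopifnot(all(lo < hi), all(scale %in% c("linear", "log")),
            all(lo[scale == "log"] > 0))
  structure(
    list(names = names(dims), scale = scale, round = rnd,
         lower = ifelse(scale == "log", log10(lo), lo),
         upper = ifelse(scale == "log", log10(hi), hi)),
    class = "sae_space"
  )
}

#' Decode a search-space point into a training control
#'
#' @param point Numeric vector on the internal search scale, one entry per
#'   space dimension.
#' @param space A [sae_space()].
#' @param base A [sae_control()] supplying every field the space does not
#'   touch.
#' @return A [sae_control()].
#' @export
decode_sae_point <- function(point, space, base = sae_control()) {
  stopifnot(inherits(space, "sae_space"), length(point) == length(space$names))
  ctl <- unclass(base)
  point <- unname(point)
  for (i in seq_along(space$names)) {
    v <- if (space$scale[i] == "log") 10^point[i] else point[i]
    if (space$round[i]) v <- as.integer(round(v))
    nm <- space$names[i]
    if (grepl("^hidden[0-9]+$", nm)) {
      idx <- as.integer(sub("hidden", "", nm))
      if (idx > length(ctl$hidden_sizes)) {
        ctl$hidden_sizes <- c(ctl$hidden_sizes,
                              rep(ctl$hidden_sizes[length(ctl$hidden_sizes)],
                                  idx - length(ctl$hidden_sizes)))
      }
      ctl$hidden_sizes[idx] <- max(1L, as.integer(v))
    } else if (nm %in% names(ctl)) {
      ctl[[nm]] <- if (nm %in% c("pretrain_epochs", "finetune_epochs",
                                 "batch_size")) max(1L, as.integer(round(v))) else v
    } else {
      stop("unknown search dimension: ", nm, call. = FALSE)
    }
  }
  do.call(sae_control, ctl)
}

#' Cross-validated fitness of a hyperparameter point
#'
#' The objective the equilibrium optimizer minimizes when tuning the
#' classifier: decode the point into a training control, run stratified
#' k-fold cross-validation (train on k-1 folds, classify the held-out
#' fold), and return `1 - CA_validation` where `CA_validation` is the mean
#' fraction of correct held-out classifications across folds. A fold whose
#' training diverges scores worst-case fitness 1 (with a warning) so the
#' search continues.
#'
#' @param point Numeric vector inside the space box.
#' @param space A [sae_space()].
#' @param dataset A [pph_dataset()] (training data only).
#' @param k Number of folds. Default 10.
#' @param base A [sae_control()] for untouched fields.
#' @param seed Integer seed used for fold construction and per-fold
#'   training.
#' @return Fitness in `[0, 1]`; 0 means every held-out sample was
#'   classified correctly.
#' @export
sae_cv_fitness <- function(point, space, dataset, k = 10,
                           base = sae_control(), seed = 1) {
  stopifnot(inherits(dataset, "pph_dataset"))
  ctl <- decode_sae_point(point, space, base)
  fold <- stratified_folds(dataset$labels, k, seed = seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- dataset[fold != f, ]
    te <- dataset[fold == f, ]
    ctl$seed <- seed + f
    fit <- tryCatch(sae(tr, control = ctl), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold ", f, " training failed (", conditionMessage(fit),
              "); assigning worst-case fitness")
      return(1)
    }
    acc[f] <- mean(predict(fit, te$features) == te$labels)
  }
  1 - mean(acc)
}

#' Tune the autoencoder classifier with the equilibrium optimizer
#'
#' Runs [eo_optim()] over [sae_cv_fitness()] and decodes the best point.
#' Tuning cost is `k` trainings per particle per iteration, so budgets and
#' data are usually reduced relative to the final fit.
#'
#' @param dataset Training-split [pph_dataset()].
#' @param space A [sae_space()].
#' @param base A [sae_control()] for untouched fields (its epoch budgets
#'   bound the per-fold training cost).
#' @param k CV folds for the fitness. Default 10.
#' @param n_particles,max_iter Equilibrium-optimizer budgets. Defaults 5
#'   and 5.
#' @param seed Integer seed.
#' @param ... Further arguments to [eo_optim()].
#' @return A list of class `sae_tuning`: `best_control` (decoded
#'   [sae_control()]), `best_fitness`, `history` (non-increasing), and the
#'   raw `eo` result.
#' @export
tune_sae <- function(dataset, space = sae_space(), base = sae_control(),
                     k = 10, n_particles = 5, max_iter = 5, seed = 1, ...) {
  objective <- function(point) {
    sae_cv_fitness(point, space, dataset, k = k, base = base, seed = seed)
  }
  eo <- eo_optim(objective, space$lower, space$upper,
                 n_particles = n_particles, max_iter = max_iter,
                 seed = seed, ...)
  structure(
    list(best_control = decode_sae_point(eo$par, space, base),
         best_fitness = eo$value, history = eo$history, eo = eo),
    class = "sae_tuning"
  )
}

#' @export
print.sae_tuning <- function(x, ...) {
  cat(sprintf("<sae_tuning> best CV fitness %.4f (CV accuracy %.4f)\n",
              x$best_fitness, 1 - x$best_fitness))
  ctl <- x$best_control
  cat(sprintf("  hidden=[%s] lambda=%.3g beta=%.3g rho=%.3g lr=%.3g\n",
              paste(ctl$hidden_sizes, collapse = ","), ctl$weight_decay,
              ctl$sparsity_weight, ctl$sparsity_target, ctl$learning_rate))
  invisible(x)
}
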