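#' Binarize a continuous crow position into a feature mask
#'
#' The search keeps crow positions continuous in `[0,1]^d`; a feature is
#' included exactly when its coordinate strictly exceeds the threshold, so
#' a coordinate sitting exactly on the threshold is excluded.
#'
#' @param position Numeric vector with finite entries in `[0,1]`.
#' @param threshold Inclusion threshold in (0,1). Default 0.5.
#' @return Logical inclusion mask of the same length.
#' @examples
#' binarize_position(c(0.2, 0.7, 0.5))
#' @export
binarize_position <- function(position, threshold = 0.5) {
  stopifnot(all(is.finite(position)))
  position > threshold
}

#' Opposite flight length
#'
#' Opposition-based learning reflects a value within its bounds:
#' `fl_min + fl_max - fl`. The reflection is an involution and maps the
#' interval onto itself; trying both a flight length and its opposite lets
#' the search probe a long step whenever it drew a short one and vice versa.
#'
#' @param fl Flight length inside `[fl_min, fl_max]`.
#' @param fl_min,fl_max Bounds of the flight-length interval. Defaults 0.1
#'   and 1.8.
#' @return The reflected flight length.
#' @examples
#' opposite_fl(0.1)            # -> 1.8
#' opposite_fl(opposite_fl(0.7))
#' @export
opposite_fl <- function(fl, fl_min = 0.1, fl_max = 1.8) {
  stopifnot(fl_min < fl_max)
  if (any(fl < fl_min | fl > fl_max)) {
    stop("`fl` must lie inside [fl_min, fl_max]", call. = FALSE)
  }
  fl_min + fl_max - fl
}

#' One crow position update
#'
#' Draws the awareness coin once: with probability `1 - awareness_prob` the
#' crow follows the memorized cache of crow `j`, moving
#' `position + tau * fl * (memory - position)` with a fresh `tau ~ U(0,1)`
#' and the result clamped to `[0,1]`; otherwise the followed crow has
#' noticed the pursuit and the follower jumps to a fresh uniform random
#' position.
#'
#' @param position Current position in `[0,1]^d`.
#' @param memory Memorized best position of the followed crow, same length.
#' @param fl Flight length (step-size multiplier), `> 0`.
#' @param awareness_prob Probability the followed crow notices, in
#'   `[0,1]`. Default 0.3.
#' @return Updated position in `[0,1]^d`.
#' @export
crow_update <- function(position, memory, fl, awareness_prob = 0.3) {
  if (length(position) != length(memory)) {
    stop("`position` and `memory` must have the same length", call. = FALSE)
  }
  theta <- stats::runif(1)
  if (theta >= awareness_prob) {
    tau <- stats::runif(1)
    clamp01(position + tau * fl * (memory - position))
  } else {
    stats::runif(length(position))
  }
}

#' Wrapper feature-selection cost
#'
#' The minimized "best cost" balances classification performance against
#' subset size: `(1 - C) + W * (F_sub / F_all)`, where `C` is the
#' evaluator's cross-validated accuracy on the masked features, `F_sub` the
#' number of selected features and `F_all` the total. Lower is better; with
#' `W = 0` it is the pure classification error. `as_printed = TRUE`
#' switches to the variant `C + W * (1 - F_all / F_sub)`, retained for
#' comparison although its size term rewards tiny subsets without bound.
#'
#' @param mask Logical (or 0/1) inclusion vector; must select at least one
#'   feature.
#' @param dataset A [pph_dataset()].
#' @param evaluator Function `(dataset, mask) -> accuracy in [0,1]`.
#'   Default [knn_cv_accuracy()].
#' @param subset_weight Weight `W` of the subset-size term, in `[0,1]`.
#'   Default 0.01.
#' @param as_printed Use the alternative cost above. Default `FALSE`.
#' @return Scalar cost.
#' @examples
#' s <- synth_pph(120, 8, 3, prevalence = 0.4, seed = 7)
#' fs_cost(rep(TRUE, 8), s$dataset)
#' @export
fs_cost <- function(mask, dataset, evaluator = knn_cv_accuracy,
                    subset_weight = 0.01, as_printed = FALSE) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask is infeasible", call. = FALSE)
  f_all <- length(mask)
  f_sub <- sum(mask)
  c_acc <- evaluator(dataset, mask)
  if (as_printed) {
    c_acc + subset_weight * (1 - f_all / f_sub)
  } else {
    (1 - c_acc) + subset_weight * (f_sub / f_all)
  }
}

#' Cross-validated nearest-neighbour accuracy of a feature subset
#'
#' The cheap reference classifier used to score candidate subsets inside
#' the wrapper search: single nearest neighbour on standardized masked
#' features, evaluated by stratified k-fold cross-validation. Parameterless
#' and deterministic given `seed` (distance ties resolve to the
#' lowest-index training row), so repeated evaluations of the same mask
#' return identical accuracies and can be cached.
#'
#' @param dataset A [pph_dataset()].
#' @param mask Logical (or 0/1) feature inclusion vector.
#' @param k Number of CV folds (`>= 2`, at most the minority count).
#'   Default 5.
#' @param seed Integer seed for fold construction. Default 1.
#' @return Cross-validated accuracy in `[0, 1]`.
#' @export
knn_cv_accuracy <- function(dataset, mask, k = 5, seed = 1) {
  stopifnot(inherits(dataset, "pph_dataset"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask", call. = FALSE)
  x <- dataset$features[, mask, drop = FALSE]
  y <- dataset$labels
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  fold <- stratified_folds(y, k, seed = seed)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    pred <- nn1_predict(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE])
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

# 1-NN with deterministic lowest-index tie-break.
nn1_predict <- function(x_train, y_train, x_test) {
  # squared Euclidean distances via the expanded form; ties -> which.min
  tr_sq <- rowSums(x_train^2)
  te_sq <- rowSums(x_test^2)
  cross <- x_test %*% t(x_train)
  d2 <- outer(te_sq, tr_sq, "+") - 2 * cross
  y_train[max.col(-d2, ties.method = "first")]
}

#' Oppositional binary crow search feature selection
#'
#' Wrapper feature selection by a crow search over `[0,1]^p`. Each crow
#' keeps a continuous position (binarized at `threshold` for evaluation)
#' and a memory of its best position so far. Per iteration every crow picks
#' a random flock member to follow and draws a flight length
#' `fl ~ U(fl_min, fl_max)`; opposition-based learning evaluates the move
#' under both `fl` and its reflection [opposite_fl()] and keeps the cheaper
#' candidate. With probability `awareness_prob` the followed crow notices
#' and the crow restarts at a uniform random position. Memories update
#' greedily, so the best-cost history is non-increasing. An all-zero
#' candidate mask is assigned cost `Inf` rather than evaluated.
#'
#' @param dataset A [pph_dataset()] (typically the training split only).
#' @param n_crows Flock size. Default 25.
#' @param awareness_prob Awareness probability. Default 0.3.
#' @param fl_min,fl_max Flight-length bounds. Defaults 0.1 and 1.8.
#' @param max_iter Number of iterations. Default 100.
#' @param subset_weight Subset-size weight `W` in the cost. Default 0.01.
#' @param threshold Binarization threshold. Default 0.5.
#' @param evaluator Accuracy oracle `(dataset, mask) -> [0,1]`. Default
#'   [knn_cv_accuracy()] with its default folds.
#' @param as_printed Use the alternative cost of [fs_cost()]. Default
#'   `FALSE`.
#' @param seed Integer seed; the run is bit-reproducible from it.
#' @return An object of class `crow_fs`: `best_mask` (logical), `best_cost`,
#'   `cost_history` (length `max_iter`, non-increasing), `n_selected`,
#'   `selected` (feature names), `n_evaluations`, and the call parameters.
#' @examples
#' s <- synth_pph(150, 12, 3, prevalence = 0.4, seed = 3)
#' fit <- crow_select(s$dataset, n_crows = 6, max_iter = 5, seed = 1)
#' fit
#' @export
crow_select <- function(dataset, n_crows = 25, awareness_prob = 0.3,
                        fl_min = 0.1, fl_max = 1.8, max_iter = 100,
                        subset_weight = 0.01, threshold = 0.5,
                        evaluator = knn_cv_accuracy, as_printed = FALSE,
                        seed = 1) {
  stopifnot(inherits(dataset, "pph_dataset"), n_crows >= 2, max_iter >= 1,
            fl_min > 0, fl_min < fl_max,
            awareness_prob >= 0, awareness_prob <= 1)
  p <- ncol(dataset$features)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  cost_of <- function(position) {
    mask <- binarize_position(position, threshold)
    if (!any(mask)) return(Inf)
    key <- rawToChar(as.raw(as.integer(mask) + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_eval <<- n_eval + 1L
    cost <- fs_cost(mask, dataset, evaluator, subset_weight, as_printed)
    cache[[key]] <- cost
    cost
  }
  with_seed(seed, {
    positions <- matrix(stats::runif(n_crows * p), n_crows, p)
    memories <- positions
    memory_costs <- apply(positions, 1, cost_of)
    history <- numeric(max_iter)
    for (iter in seq_len(max_iter)) {
      for (i in seq_len(n_crows)) {
        j <- sample.int(n_crows, 1)
        theta <- stats::runif(1)
        if (theta >= awareness_prob) {
          fl <- stats::runif(1, fl_min, fl_max)
          tau <- stats::runif(1)
          step <- memories[j, ] - positions[i, ]
          cand_a <- clamp01(positions[i, ] + tau * fl * step)
          cand_b <- clamp01(positions[i, ] +
                              tau * opposite_fl(fl, fl_min, fl_max) * step)
          cost_a <- cost_of(cand_a)
          cost_b <- cost_of(cand_b)
          if (cost_a <= cost_b) {
            positions[i, ] <- cand_a; new_cost <- cost_a
          } else {
            positions[i, ] <- cand_b; new_cost <- cost_b
          }
        } else {
          positions[i, ] <- stats::runif(p)
          new_cost <- cost_of(positions[i, ])
        }
        if (new_cost < memory_costs[i]) {
          memories[i, ] <- positions[i, ]
          memory_costs[i] <- new_cost
        }
      }
      history[iter] <- min(memory_costs)
    }
    best <- which.min(memory_costs)
    best_mask <- binarize_position(memories[best, ], threshold)
    structure(
      list(best_mask = best_mask,
           best_cost = memory_costs[best],
           cost_history = history,
           n_selected = sum(best_mask),
           selected = dataset$feature_names[best_mask],
           n_evaluations = n_eval,
           n_features = p,
           params = list(n_crows = n_crows, awareness_prob = awareness_prob,
                         fl_min = fl_min, fl_max = fl_max,
                         max_iter = max_iter, subset_weight = subset_weight,
                         threshold = threshold, as_printed = as_printed,
                         seed = seed)),
      class = "crow_fs"
    )
  })
}

#' @export
print.crow_fs <- function(x, ...) {
  cat(sprintf("<crow_fs> %d of %d features selected; best cost %.5f (%d subset evaluations)\n",
              x$n_selected, x$n_features, x$best_cost, x$n_evaluations))
  invisible(x)
}

#' @export
plot.crow_fs <- function(x, ...) {
  plot(seq_along(x$cost_history), x$cost_history, type = "s",
       xlab = "iteration", ylab = "best cost", ...)
  invisible(x)
}
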