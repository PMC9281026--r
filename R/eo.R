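#' Time parameter of the equilibrium optimizer
#'
#' `t = (1 - Iter/Max_iter) ^ (a2 * Iter/Max_iter)`: decays from 1 at the
#' first iteration to 0 at the last, shrinking the exponential term and
#' shifting the search from exploration to exploitation. `as_printed = TRUE`
#' evaluates the same two factors as a product instead of a power, a
#' variant that pins `t` to 0 at iteration 0 and is kept only for
#' comparison.
#'
#' @param iter Current iteration, `0 <= iter <= max_iter`.
#' @param max_iter Total iterations.
#' @param a2 Exploitation-control constant. Default 1.
#' @param as_printed Use the product variant. Default `FALSE`.
#' @return Scalar `t` in `[0, 1]`.
#' @examples
#' eo_time_param(0, 100)    # 1
#' eo_time_param(100, 100)  # 0
#' @export
eo_time_param <- function(iter, max_iter, a2 = 1, as_printed = FALSE) {
  if (iter < 0 || iter > max_iter) stop("`iter` out of range", call. = FALSE)
  frac <- iter / max_iter
  if (as_printed) (1 - frac) * (a2 * frac) else (1 - frac)^(a2 * frac)
}

#' Exponential term F
#'
#' `F = a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)` elementwise, with
#' `r ~ U(0,1)` per dimension; the sign flip makes half the moves explore
#' away from the attractor. `sign(0)` is 0, so an exact `r = 0.5` draw
#' yields no move in that dimension. `|F| <= a1 * (1 - exp(-lambda * t))`.
#'
#' @param lambda_vec Turnover-rate vector in (0,1).
#' @param t Time parameter from [eo_time_param()], `>= 0`.
#' @param a1 Exploration-control constant. Default 2.
#' @param r Optional uniform draws (same length as `lambda_vec`); defaults
#'   to fresh `runif` draws.
#' @return Vector `F`.
#' @export
eo_exponential_term <- function(lambda_vec, t, a1 = 2, r = NULL) {
  stopifnot(t >= 0)
  if (is.null(r)) r <- stats::runif(length(lambda_vec))
  a1 * sign(r - 0.5) * (exp(-lambda_vec * t) - 1)
}

#' Generation rate G
#'
#' Draws `r1, r2 ~ U(0,1)` (once per particle); the generation-rate control
#' parameter is `GCP = 0.5 * r1` when `r2 >= generation_prob` and 0
#' otherwise, shared across dimensions. Then `G0 = GCP * (C_eq - lambda*C)`
#' and `G = G0 * F`.
#'
#' @param C Current concentration vector.
#' @param C_eq Attractor drawn from the equilibrium pool.
#' @param lambda_vec Turnover-rate vector.
#' @param F_vec Exponential term from [eo_exponential_term()].
#' @param generation_prob Generation probability `GP` in `[0,1]`.
#'   Default 0.5.
#' @param r1,r2 Optional uniform draws; default fresh `runif(1)` draws.
#' @return Vector `G`.
#' @export
eo_generation_rate <- function(C, C_eq, lambda_vec, F_vec,
                               generation_prob = 0.5, r1 = NULL, r2 = NULL) {
  stopifnot(length(C) == length(C_eq), length(C) == length(F_vec))
  if (is.null(r1)) r1 <- stats::runif(1)
  if (is.null(r2)) r2 <- stats::runif(1)
  gcp <- if (r2 >= generation_prob) 0.5 * r1 else 0
  gcp * (C_eq - lambda_vec * C) * F_vec
}

#' Concentration update
#'
#' `C_new = C_eq + (C - C_eq)*F + (G / (lambda * V)) * (1 - F)`, clamped to
#' the box. The three terms are the equilibrium concentration itself, a
#' global-search pull of the current state toward it, and a local-search
#' generation-rate correction. `F = 0, G = 0` collapses onto the attractor;
#' `F = 1, G = 0` leaves the particle in place.
#'
#' @param C,C_eq,lambda_vec,F_vec,G_vec Vectors of equal length;
#'   `lambda_vec` entries `> 0`.
#' @param V Control volume. Default 1.
#' @param lower,upper Optional box bounds for clamping.
#' @return Updated concentration vector.
#' @examples
#' eo_update_concentration(2, 1, lambda_vec = 0.5, F_vec = 0.5, G_vec = 0.1)
#' @export
eo_update_concentration <- function(C, C_eq, lambda_vec, F_vec, G_vec, V = 1,
                                    lower = NULL, upper = NULL) {
  stopifnot(all(lambda_vec > 0), V > 0)
  out <- C_eq + (C - C_eq) * F_vec + (G_vec / (lambda_vec * V)) * (1 - F_vec)
  if (!is.null(lower)) out <- pmax(out, lower)
  if (!is.null(upper)) out <- pmin(out, upper)
  out
}

#' Equilibrium optimizer over a bounded box
#'
#' Population metaheuristic in which candidate "concentrations" relax
#' toward an equilibrium pool — the four best solutions found so far plus
#' their elementwise mean. Per iteration each particle draws a pool member
#' uniformly, a turnover vector `lambda ~ U(0,1)^d`, the exponential term
#' `F` and generation rate `G`, and moves by [eo_update_concentration()].
#' The pool is updated greedily, so the best-cost history is
#' non-increasing.
#'
#' @param fn Objective to minimize; must return a finite scalar on the box.
#' @param lower,upper Numeric bound vectors, `lower < upper` elementwise.
#' @param n_particles Population size. Default 30.
#' @param max_iter Iterations. Default 200.
#' @param a1,a2 Exploration/exploitation constants. Defaults 2 and 1.
#' @param generation_prob Generation probability. Default 0.5.
#' @param V Control volume. Default 1.
#' @param seed Integer seed; the run is bit-reproducible from it.
#' @return An object of class `eo_optim`: `par` (best point), `value`
#'   (best cost), `history` (best cost after each iteration, length
#'   `max_iter + 1` including the initial population), `n_evaluations`.
#' @examples
#' fit <- eo_optim(function(x) sum(x^2), c(-10, -10), c(10, 10),
#'                 n_particles = 15, max_iter = 50, seed = 1)
#' fit$value
#' @export
eo_optim <- function(fn, lower, upper, n_particles = 30, max_iter = 200,
                     a1 = 2, a2 = 1, generation_prob = 0.5, V = 1, seed = 1) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower <= upper),
            n_particles >= 1, max_iter >= 1)
  d <- length(lower)
  evaluate <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) stop("objective returned a non-finite value", call. = FALSE)
    v
  }
  with_seed(seed, {
    C <- matrix(stats::runif(n_particles * d), n_particles, d)
    C <- sweep(sweep(C, 2, upper - lower, "*"), 2, lower, "+")
    costs <- apply(C, 1, evaluate)
    n_eval <- n_particles
    # equilibrium pool: four best-so-far concentrations, sorted by cost
    ord <- order(costs)[seq_len(min(4, n_particles))]
    pool <- C[ord, , drop = FALSE]
    pool_costs <- costs[ord]
    while (nrow(pool) < 4) {       # tiny populations: pad with the best
      pool <- rbind(pool, pool[1, ])
      pool_costs <- c(pool_costs, pool_costs[1])
    }
    history <- numeric(max_iter + 1L)
    history[1] <- pool_costs[1]
    for (iter in seq_len(max_iter)) {
      t <- eo_time_param(iter, max_iter, a2)
      pool_ave <- colMeans(pool)
      for (i in seq_len(n_particles)) {
        pick <- sample.int(5, 1)
        C_eq <- if (pick == 5) pool_ave else pool[pick, ]
        lambda_vec <- stats::runif(d)
        F_vec <- eo_exponential_term(lambda_vec, t, a1)
        G_vec <- eo_generation_rate(C[i, ], C_eq, lambda_vec, F_vec,
                                    generation_prob)
        C[i, ] <- eo_update_concentration(C[i, ], C_eq, lambda_vec, F_vec,
                                          G_vec, V, lower, upper)
        costs[i] <- evaluate(C[i, ])
        n_eval <- n_eval + 1L
        # greedy pool update (stable order: incumbents win ties)
        if (costs[i] < pool_costs[4]) {
          cand <- rbind(pool, C[i, ])
          cand_costs <- c(pool_costs, costs[i])
          keep <- order(cand_costs)[1:4]
          pool <- cand[keep, , drop = FALSE]
          pool_costs <- cand_costs[keep]
        }
      }
      history[iter + 1L] <- pool_costs[1]
    }
    structure(
      list(par = pool[1, ], value = pool_costs[1], history = history,
           n_evaluations = n_eval,
           params = list(n_particles = n_particles, max_iter = max_iter,
                         a1 = a1, a2 = a2, generation_prob = generation_prob,
                         V = V, seed = seed)),
      class = "eo_optim"
    )
  })
}

#' @export
print.eo_optim <- function(x, ...) {
  cat(sprintf("<eo_optim> best cost %.6g after %d evaluations\n",
              x$value, x$n_evaluations))
  cat("  par:", format(x$par, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.eo_optim <- function(x, ...) {
  plot(seq_along(x$history) - 1L, x$history, type = "s", xlab = "iteration",
       ylab = "best cost", ...)
  invisible(x)
}
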