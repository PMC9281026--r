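test_that("binarization uses a strict threshold", {
  expect_equal(binarize_position(rep(0.9, 4)), rep(TRUE, 4))
  expect_equal(binarize_position(c(0.2, 0.7, 0.5)), c(FALSE, TRUE, FALSE))
  expect_false(binarize_position(0.5))          # exactly at threshold: out
  expect_error(binarize_position(c(0.1, NA)))
})

test_that("the opposite flight length is an involution within its bounds", {
  expect_equal(opposite_fl(0.1), 1.8)
  expect_equal(opposite_fl(1.8), 0.1)
  expect_equal(opposite_fl(0.95), 0.95)          # midpoint fixed point
  for (fl in seq(0.1, 1.8, by = 0.17)) {
    expect_equal(opposite_fl(opposite_fl(fl)), fl, tolerance = 1e-12)
    expect_gte(opposite_fl(fl), 0.1)
    expect_lte(opposite_fl(fl), 1.8)
  }
  expect_equal(opposite_fl(2, fl_min = 1, fl_max = 5), 4)
  expect_error(opposite_fl(2.5), "inside")
})

test_that("crow position updates follow the memory-pursuit rule", {
  set.seed(1)
  # memory = position: a followed move never leaves the point
  for (i in 1:20) {
    p <- runif(6)
    expect_equal(crow_update(p, p, fl = 1.3, awareness_prob = 0), p)
  }
  # vanishing flight length: no move
  p <- runif(6); m <- runif(6)
  expect_equal(crow_update(p, m, fl = 1e-12, awareness_prob = 0), p,
               tolerance = 1e-9)
  # clamping: pursuing memory 1 from 0.5 with fl = 1.8 overshoots past 1
  # (raw value 0.5 + 1.8*tau*0.5 > 1 whenever tau > 5/9) and is clamped
  hits_one <- replicate(60, crow_update(0.5, 1.0, fl = 1.8,
                                        awareness_prob = 0))
  expect_true(all(hits_one >= 0.5 & hits_one <= 1))
  expect_true(any(hits_one == 1))
  # awareness = 1: always a fresh uniform jump, independent of memory
  set.seed(2)
  jumps <- replicate(200, crow_update(0.5, 0.5, fl = 1, awareness_prob = 1))
  expect_gt(max(jumps), 0.9); expect_lt(min(jumps), 0.1)
  expect_error(crow_update(runif(3), runif(4), 1), "length")
})

test_that("the wrapper cost trades accuracy against subset size", {
  d <- two_cluster_dataset(n = 20, d = 149, seed = 2)
  const_eval <- function(c_val) function(dataset, mask) c_val
  mask15 <- rep(c(TRUE, FALSE), c(15, 134))
  expect_equal(fs_cost(mask15, d, const_eval(0.95), subset_weight = 0.01),
               0.05 + 0.01 * 15 / 149, tolerance = 1e-12)
  expect_equal(fs_cost(rep(TRUE, 149), d, const_eval(1), subset_weight = 0.3),
               0.3, tolerance = 1e-12)
  expect_equal(fs_cost(mask15, d, const_eval(0.8), subset_weight = 0),
               0.2, tolerance = 1e-12)
  # literal printed variant retained behind a flag
  expect_equal(fs_cost(mask15, d, const_eval(0.95), subset_weight = 0.01,
                       as_printed = TRUE),
               0.95 + 0.01 * (1 - 149 / 15), tolerance = 1e-12)
  expect_error(fs_cost(rep(FALSE, 149), d, const_eval(1)), "empty")
})

test_that("the nearest-neighbour surrogate scores subsets sensibly", {
  d <- two_cluster_dataset(n = 60, d = 4, gap = 8, seed = 3)
  expect_equal(knn_cv_accuracy(d, rep(TRUE, 4), k = 5, seed = 1), 1)
  # permuted labels on featureless data: near chance
  set.seed(4)
  null_d <- pph_dataset(matrix(rnorm(200 * 4), 200, 4), rep(c(0, 1), 100))
  acc_null <- knn_cv_accuracy(null_d, rep(TRUE, 4), k = 5, seed = 1)
  expect_lt(abs(acc_null - 0.5), 0.12)
  # adding pure-noise features must not beat the informative-only subset
  # by more than CV noise
  s <- synth_pph(300, 10, 3, prevalence = 0.4, effect_size = 2, seed = 5)
  acc_inf <- knn_cv_accuracy(s$dataset, rep(c(TRUE, FALSE), c(3, 7)),
                             k = 5, seed = 1)
  acc_all <- knn_cv_accuracy(s$dataset, rep(TRUE, 10), k = 5, seed = 1)
  expect_lt(acc_all, acc_inf + 0.05)
  # deterministic: repeated calls identical
  expect_identical(acc_all, knn_cv_accuracy(s$dataset, rep(TRUE, 10),
                                            k = 5, seed = 1))
})

test_that("the crow search keeps its bookkeeping invariants", {
  d <- two_cluster_dataset(n = 30, d = 6, seed = 6)
  ev <- planted_evaluator(1:2)
  for (seed in 1:3) {
    fit <- crow_select(d, n_crows = 5, max_iter = 12, evaluator = ev,
                       seed = seed)
    expect_true(all(diff(fit$cost_history) <= 1e-12))
    expect_length(fit$cost_history, 12)
    expect_equal(fit$best_cost, min(fit$cost_history))
    expect_equal(fit$n_selected, sum(fit$best_mask))
    expect_gte(fit$n_selected, 1)
  }
  # determinism
  a <- crow_select(d, n_crows = 5, max_iter = 6, evaluator = ev, seed = 9)
  b <- crow_select(d, n_crows = 5, max_iter = 6, evaluator = ev, seed = 9)
  expect_identical(a, b)
  # one iteration: history has a single entry equal to the best cost
  one <- crow_select(d, n_crows = 5, max_iter = 1, evaluator = ev, seed = 2)
  expect_length(one$cost_history, 1)
  expect_equal(one$best_cost, one$cost_history[1])
})

test_that("with full awareness every move is a restart and flight length is inert", {
  d <- two_cluster_dataset(n = 30, d = 6, seed = 7)
  ev <- planted_evaluator(1:2)
  narrow <- crow_select(d, n_crows = 5, max_iter = 10, awareness_prob = 1,
                        fl_min = 0.1, fl_max = 0.2, evaluator = ev, seed = 3)
  wide <- crow_select(d, n_crows = 5, max_iter = 10, awareness_prob = 1,
                      fl_min = 0.5, fl_max = 1.8, evaluator = ev, seed = 3)
  narrow$params <- wide$params <- NULL
  expect_identical(narrow, wide)
})

test_that("the search never beats, and can reach, the exhaustive optimum", {
  d <- 8
  ds <- two_cluster_dataset(n = 20, d = d, seed = 8)
  ev <- planted_evaluator(1:3)
  opt <- exhaustive_best_cost(d, ds, ev, subset_weight = 0.01)
  for (seed in 1:4) {
    fit <- crow_select(ds, n_crows = 8, max_iter = 25, evaluator = ev,
                       subset_weight = 0.01, seed = seed)
    expect_gte(fit$best_cost, opt - 1e-12)
  }
  # easy planted instance (steep noise penalty): the optimum is reached
  ev_easy <- planted_evaluator(1:3, penalty = 0.2)
  opt_easy <- exhaustive_best_cost(d, ds, ev_easy, subset_weight = 0.01)
  fit <- crow_select(ds, n_crows = 10, max_iter = 40, evaluator = ev_easy,
                     subset_weight = 0.01, seed = 1)
  expect_equal(fit$best_cost, opt_easy, tolerance = 1e-12)
  expect_equal(sort(which(fit$best_mask)), 1:3)
})

test_that("wrapper selection recovers planted features beyond chance", {
  s <- synth_pph(400, 40, 6, prevalence = 0.3, effect_size = 1.5, seed = 10)
  fit <- crow_select(s$dataset, n_crows = 8, max_iter = 15,
                     evaluator = function(dataset, mask) {
                       knn_cv_accuracy(dataset, mask, k = 3, seed = 1)
                     }, seed = 4)
  overlap <- sum(which(fit$best_mask) %in% s$informative)
  # one-sided hypergeometric tail at the observed subset size
  p_chance <- stats::phyper(overlap - 1, 6, 34, fit$n_selected,
                            lower.tail = FALSE)
  expect_lt(p_chance, 0.01)
})
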