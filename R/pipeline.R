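#' End-to-end prediction pipeline with repeated runs
#'
#' Orchestrates the full procedure over `n_runs` independent repetitions:
#' for run `r` a per-run seed `master_seed + r` drives a stratified
#' train/test split, crow-search feature selection on the training split,
#' equilibrium-optimizer hyperparameter tuning on the training split
#' restricted to the selected features, a final classifier fit on that
#' training data, and evaluation on the untouched test split. No test-split
#' sample reaches feature selection or tuning. The whole procedure is
#' bit-reproducible from `master_seed`.
#'
#' The default budgets are a desk-scale smoke profile (small flock, few
#' iterations, 3-fold tuning CV) intended for datasets of a few hundred
#' records; for a full-scale cohort raise them toward the reference budgets
#' (`fs_args = list(n_crows = 25, max_iter = 100)`, `cv_k = 10`).
#'
#' @param dataset A [pph_dataset()].
#' @param n_runs Number of repeated runs. Default 10.
#' @param test_fraction Held-out fraction per run. Default 0.3.
#' @param fs_args Named list of overrides for [crow_select()] (budget,
#'   weights, ...).
#' @param tune Logical: run hyperparameter tuning? Default `TRUE`.
#' @param space A [sae_space()] for tuning.
#' @param base_control A [sae_control()]: the fallback (and tuning base)
#'   configuration.
#' @param tune_args Named list of overrides for [tune_sae()]
#'   (`n_particles`, `max_iter`).
#' @param cv_k Folds of the tuning cross-validation. Default 3.
#' @param reselect_features Re-run feature selection every run (`TRUE`,
#'   default) or reuse the first run's mask.
#' @param master_seed Integer master seed. Default 1.
#' @return An object of class `pph_pipeline`: `runs` (per-run artifacts:
#'   feature-selection result, tuned control, fitted model, test-set
#'   [evaluation_report()], split indices) and `aggregate` (the mean
#'   metrics row across successful runs). Runs that fail are recorded as
#'   error entries and skipped in the aggregate.
#' @examples
#' \donttest{
#' s <- synth_pph(300, 12, 3, prevalence = 0.3, seed = 2)
#' res <- pph_pipeline(s$dataset, n_runs = 2,
#'   fs_args = list(n_crows = 4, max_iter = 3),
#'   base_control = sae_control(hidden_sizes = 4, pretrain_epochs = 3,
#'                              finetune_epochs = 5),
#'   tune_args = list(n_particles = 2, max_iter = 1), master_seed = 7)
#' res
#' }
#' @export
pph_pipeline <- function(dataset, n_runs = 10, test_fraction = 0.3,
                         fs_args = list(), tune = TRUE, space = sae_space(),
                         base_control = sae_control(),
                         tune_args = list(), cv_k = 3,
                         reselect_features = TRUE, master_seed = 1) {
  stopifnot(inherits(dataset, "pph_dataset"), n_runs >= 1)
  runs <- vector("list", n_runs)
  first_fs <- NULL
  for (r in seq_len(n_runs)) {
    seed_r <- master_seed + r
    runs[[r]] <- tryCatch({
      split <- stratified_split(dataset, test_fraction, seed = seed_r)
      fs <- if (reselect_features || is.null(first_fs)) {
        do.call(crow_select,
                c(list(dataset = split$train, seed = seed_r), fs_args))
      } else {
        first_fs
      }
      if (is.null(first_fs)) first_fs <- fs
      train_sel <- split$train[, fs$best_mask]
      tuned <- if (tune) {
        do.call(tune_sae, c(list(dataset = train_sel, space = space,
                                 base = base_control, k = cv_k,
                                 seed = seed_r), tune_args))
      } else {
        NULL
      }
      ctl <- if (is.null(tuned)) base_control else tuned$best_control
      ctl$seed <- seed_r
      fit <- sae(train_sel, control = ctl)
      test_x <- split$test$features[, fs$best_mask, drop = FALSE]
      prob <- predict(fit, test_x, type = "prob")
      pred <- fit$classes[max.col(prob, ties.method = "first")]
      report <- evaluation_report(split$test$labels, pred,
                                  scores = prob[, "1"], run_id = r)
      list(seed = seed_r, fs = fs, tuning = tuned, control = ctl,
           model = fit, report = report,
           train_idx = split$train_idx, test_idx = split$test_idx)
    }, error = function(e) {
      structure(list(seed = seed_r, run_id = r,
                     message = conditionMessage(e)),
                class = "pph_run_error")
    })
  }
  ok <- !vapply(runs, inherits, logical(1), "pph_run_error")
  if (!any(ok)) stop("every pipeline run failed", call. = FALSE)
  aggregate <- aggregate_reports(lapply(runs[ok], `[[`, "report"))
  structure(
    list(runs = runs, aggregate = aggregate, n_runs = n_runs,
         master_seed = master_seed),
    class = "pph_pipeline"
  )
}

#' @export
print.pph_pipeline <- function(x, digits = 4, ...) {
  ok <- !vapply(x$runs, inherits, logical(1), "pph_run_error")
  cat(sprintf("<pph_pipeline> %d/%d runs completed (master seed %d)\n",
              sum(ok), x$n_runs, x$master_seed))
  print(summary(x, digits = digits))
  invisible(x)
}

#' @export
summary.pph_pipeline <- function(object, digits = 4, ...) {
  ok <- !vapply(object$runs, inherits, logical(1), "pph_run_error")
  rows <- lapply(object$runs[ok], function(r) run_row(r$report, r$fs))
  avg <- run_row(object$aggregate, NULL)
  tab <- do.call(rbind, c(rows, list(avg)))
  rownames(tab) <- c(paste0("run-", which(ok)), "average")
  round(tab, digits)
}

run_row <- function(report, fs) {
  c(precision = report$precision, recall = report$recall,
    accuracy = report$accuracy, f_score = report$f_score, mcc = report$mcc,
    error_rate = report$error_rate, auc = report$auc,
    n_selected = if (is.null(fs)) NA_real_ else fs$n_selected)
}

#' Write a machine-readable pipeline report
#'
#' Emits a JSON file with per-run metrics, the average row, selected
#' features, tuned hyperparameters and seeds, plus a plain-text summary
#' table next to it.
#'
#' @param result A [pph_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "pph_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- !vapply(result$runs, inherits, logical(1), "pph_run_error")
  per_run <- lapply(result$runs, function(r) {
    if (inherits(r, "pph_run_error")) {
      return(list(seed = r$seed, error = r$message))
    }
    ctl <- r$control
    list(seed = r$seed,
         metrics = r$report[c("precision", "recall", "accuracy", "f_score",
                              "mcc", "error_rate", "auc")],
         n_selected = r$fs$n_selected,
         selected_features = r$fs$selected,
         fs_best_cost = r$fs$best_cost,
         hyperparameters = list(hidden_sizes = ctl$hidden_sizes,
                                weight_decay = ctl$weight_decay,
                                sparsity_weight = ctl$sparsity_weight,
                                sparsity_target = ctl$sparsity_target,
                                learning_rate = ctl$learning_rate,
                                batch_size = ctl$batch_size))
  })
  payload <- list(
    package_version = as.character(utils::packageVersion("crowsae")),
    master_seed = result$master_seed,
    n_runs = result$n_runs,
    runs = per_run,
    average = result$aggregate[c("precision", "recall", "accuracy", "f_score",
                                 "mcc", "error_rate", "auc")]
  )
  json_path <- file.path(dir, "pipeline_report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt_path <- file.path(dir, "pipeline_report.txt")
  out <- utils::capture.output(print(summary(result)))
  writeLines(out, txt_path)
  invisible(c(json = json_path, text = txt_path))
}
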