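#' Two-by-two confusion matrix
#'
#' Cross-tabulates true and predicted binary labels. The positive class is
#' class 1 (hemorrhage present — the minority class in the cohorts this
#' package targets).
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal, positive length.
#' @return An object of class `pph_confusion`: a list with integer counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  structure(
    list(tp = sum(y_true == 1 & y_pred == 1),
         fp = sum(y_true == 0 & y_pred == 1),
         tn = sum(y_true == 0 & y_pred == 0),
         fn = sum(y_true == 1 & y_pred == 0)),
    class = "pph_confusion"
  )
}

#' @export
print.pph_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the six standard binary-classification summaries: precision
#' `tp/(tp+fp)`, recall `tp/(tp+fn)`, accuracy `(tp+tn)/n`, F-score (the
#' harmonic mean of precision and recall), Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, and error rate
#' `1 - accuracy`. A ratio with a zero denominator is reported as 0 and the
#' `degenerate` flag is set, so imbalanced runs never abort mid-pipeline.
#'
#' @param cm A [confusion_counts()] object, or a pair `y_true, y_pred`
#'   passed positionally.
#' @param y_pred Optional predicted labels if `cm` is a truth vector.
#' @return A list with `precision`, `recall`, `accuracy`, `f_score`, `mcc`,
#'   `error_rate`, `degenerate` (logical) and the `confusion` counts.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
classification_metrics <- function(cm, y_pred = NULL) {
  if (!inherits(cm, "pph_confusion")) cm <- confusion_counts(cm, y_pred)
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  accuracy <- (tp + tn) / n
  f_score <- if (precision + recall == 0) { degenerate <- TRUE; 0 } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) { degenerate <- TRUE; 0 } else {
    (tp * tn - fp * fn) / mcc_den
  }
  list(precision = precision, recall = recall, accuracy = accuracy,
       f_score = f_score, mcc = mcc, error_rate = 1 - accuracy,
       degenerate = degenerate, confusion = cm)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (tied scores
#' are grouped, so ties contribute diagonal segments) and integrates the
#' curve by the trapezoidal rule. Higher scores must indicate the positive
#' class.
#'
#' @param y_true Binary 0/1 vector containing both classes.
#' @param scores Numeric score vector of the same length.
#' @return A list with `fpr`, `tpr` (curve vertices from (0,0) to (1,1))
#'   and `auc`.
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  # indices at which a group of tied scores ends
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluation report for one run
#'
#' Wraps the six confusion-matrix metrics and (when scores are supplied)
#' the ROC AUC for one train/evaluate run.
#'
#' @param y_true,y_pred Binary 0/1 vectors.
#' @param scores Optional positive-class scores for the AUC.
#' @param run_id Optional integer identifier.
#' @return An object of class `pph_report`.
#' @export
evaluation_report <- function(y_true, y_pred, scores = NULL, run_id = NA_integer_) {
  met <- classification_metrics(confusion_counts(y_true, y_pred))
  met$auc <- if (!is.null(scores) && length(unique(y_true)) == 2L) {
    roc_auc(y_true, scores)$auc
  } else {
    NA_real_
  }
  met$run_id <- run_id
  class(met) <- "pph_report"
  met
}

#' @export
print.pph_report <- function(x, digits = 4, ...) {
  cat(sprintf("<pph_report run %s>\n", format(x$run_id)))
  v <- unlist(x[c("precision", "recall", "accuracy", "f_score", "mcc",
                  "error_rate", "auc")])
  print(round(v, digits))
  invisible(x)
}

#' Average metrics over repeated runs
#'
#' Arithmetic mean of each scalar metric across a list of run reports, as
#' used for the "average row" of a multi-run results table. Values are kept
#' at full precision; round for display.
#'
#' @param reports Non-empty list of [evaluation_report()] objects (or plain
#'   lists carrying the same scalar fields).
#' @return A `pph_report` whose scalar fields are the across-run means and
#'   whose `run_id` is `NA`.
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0L) stop("no reports to aggregate", call. = FALSE)
  fields <- c("precision", "recall", "accuracy", "f_score", "mcc",
              "error_rate", "auc")
  out <- lapply(fields, function(f) {
    vals <- vapply(reports, function(r) {
      v <- r[[f]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    mean(vals)
  })
  names(out) <- fields
  out$degenerate <- any(vapply(reports, function(r) isTRUE(r$degenerate),
                               logical(1)))
  out$confusion <- NULL
  out$run_id <- NA_integer_
  class(out) <- "pph_report"
  out
}
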