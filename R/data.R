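#' Construct a clinical tabular dataset
#'
#' Bundles a numeric feature matrix (rows = delivery records, columns =
#' clinical features) with a binary outcome vector (1 = postpartum
#' hemorrhage present) and feature names. All downstream stages — feature
#' selection, hyperparameter tuning, classification, evaluation — operate
#' on this container.
#'
#' @param features Numeric matrix, `n_samples x n_features`, all entries
#'   finite.
#' @param labels Vector of 0/1 outcomes, length `n_samples`.
#' @param feature_names Optional character vector of column names; defaults
#'   to the matrix column names or `f1, f2, ...`.
#' @return An object of class `pph_dataset`: a list with elements
#'   `features`, `labels` (integer 0/1) and `feature_names`.
#' @examples
#' d <- pph_dataset(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' d
#' @export
pph_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) == 0L || ncol(features) == 0L) {
    stop("dataset must have at least one sample and one feature", call. = FALSE)
  }
  if (!all(is.finite(features))) {
    stop("feature matrix contains missing or non-finite entries", call. = FALSE)
  }
  labels <- as.vector(labels)
  if (length(labels) != nrow(features)) {
    stop("length of `labels` must equal the number of rows of `features`",
         call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must contain only 0 and 1", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- paste0("f", seq_len(ncol(features)))
    }
  }
  if (length(feature_names) != ncol(features)) {
    stop("`feature_names` must have one entry per feature column", call. = FALSE)
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = as.integer(labels),
         feature_names = as.character(feature_names)),
    class = "pph_dataset"
  )
}

#' @export
print.pph_dataset <- function(x, ...) {
  cat(sprintf("<pph_dataset> %d samples x %d features; %d positive (%.2f%%)\n",
              nrow(x$features), ncol(x$features), sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

#' Subset a dataset by rows and/or feature columns
#'
#' @param x A [pph_dataset()].
#' @param i Row indices (samples); missing keeps all.
#' @param j Column indices or a logical feature mask; missing keeps all.
#' @param ... Unused.
#' @return A `pph_dataset`.
#' @export
`[.pph_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$features))
  if (missing(j)) j <- seq_len(ncol(x$features))
  pph_dataset(x$features[i, j, drop = FALSE], x$labels[i],
              x$feature_names[if (is.logical(j)) which(j) else j])
}

#' Read a case table from CSV
#'
#' Expects a header row, comma delimiter, a decimal point and one column of
#' 0/1 outcome labels; every other column must be numeric with no missing
#' values (records with missing measurements are rejected rather than
#' imputed).
#'
#' @param path Path to a CSV file.
#' @param label_column Name of the outcome column. Default `"pph"`.
#' @return A [pph_dataset()]; row order is preserved.
#' @export
read_pph_csv <- function(path, label_column = "pph") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty table: ", path, call. = FALSE)
  if (!label_column %in% names(tab)) {
    stop(sprintf("label column '%s' not present in %s", label_column, path),
         call. = FALSE)
  }
  labels <- tab[[label_column]]
  feat <- tab[setdiff(names(tab), label_column)]
  bad <- !vapply(feat, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric feature column(s): ",
         paste(names(feat)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(feat)
  if (!all(is.finite(m))) {
    stop("missing or non-finite feature values in ", path, call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("label column contains values outside {0, 1}", call. = FALSE)
  }
  pph_dataset(m, labels, names(feat))
}

#' Write a case table to CSV
#'
#' Inverse of [read_pph_csv()]: writes the feature columns under their
#' feature names plus the label column.
#'
#' @param dataset A [pph_dataset()].
#' @param path Destination path.
#' @param label_column Name for the outcome column. Default `"pph"`.
#' @return `path`, invisibly.
#' @export
write_pph_csv <- function(dataset, path, label_column = "pph") {
  stopifnot(inherits(dataset, "pph_dataset"))
  tab <- as.data.frame(dataset$features, check.names = FALSE)
  tab[[label_column]] <- dataset$labels
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Generate a synthetic postpartum-hemorrhage-like cohort
#'
#' Emulates the shape of a large obstetric cohort: many records, wide
#' clinical feature panel, strong class imbalance, and a small planted
#' subset of informative features. Labels are Bernoulli(`prevalence`)
#' (or a fixed positive count with `fixed_count = TRUE`); informative
#' columns are Normal(`effect_size * label * noise_sd`, `noise_sd^2`) so
#' the positive class is mean-shifted by `effect_size` standard deviations;
#' the remaining columns are pure Normal(0, `noise_sd^2`) noise.
#'
#' Defaults reproduce the cohort shape the package targets: 11,000 records,
#' 149 features, prevalence 1042/11000 (~9.47%), 15 informative features.
#'
#' @param n_samples Number of records. Default 11000.
#' @param n_features Number of feature columns. Default 149.
#' @param n_informative Number of planted informative columns (the first
#'   `n_informative` columns). Default 15.
#' @param prevalence Positive-class probability, in (0,1). Default
#'   `1042/11000`.
#' @param effect_size Class-conditional mean shift of informative columns,
#'   in units of `noise_sd`. Default 1.5.
#' @param noise_sd Standard deviation of all columns. Default 1.
#' @param seed Integer seed; generation is bit-reproducible from it.
#' @param fixed_count If `TRUE`, draw exactly `round(n_samples * prevalence)`
#'   positives (at random positions) instead of independent Bernoulli labels.
#' @return A list with `dataset` (a [pph_dataset()]) and `informative`
#'   (integer indices of the planted informative columns).
#' @examples
#' s <- synth_pph(n_samples = 200, n_features = 10, n_informative = 3, seed = 1)
#' s$dataset
#' s$informative
#' @export
synth_pph <- function(n_samples = 11000, n_features = 149, n_informative = 15,
                      prevalence = 1042 / 11000, effect_size = 1.5,
                      noise_sd = 1, seed = 1, fixed_count = FALSE) {
  stopifnot(n_samples >= 1, n_features >= 1,
            n_informative >= 1, n_informative <= n_features,
            effect_size >= 0, noise_sd > 0)
  stopifnot_scalar_prob(prevalence, "prevalence")
  with_seed(seed, {
    labels <- if (fixed_count) {
      n_pos <- round(n_samples * prevalence)
      lab <- integer(n_samples)
      lab[sample.int(n_samples, n_pos)] <- 1L
      lab
    } else {
      as.integer(stats::runif(n_samples) < prevalence)
    }
    x <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                n_samples, n_features)
    shift <- effect_size * noise_sd
    x[, seq_len(n_informative)] <-
      x[, seq_len(n_informative), drop = FALSE] + shift * labels
    pph_dataset(x, labels)
  }) -> dataset
  list(dataset = dataset, informative = seq_len(n_informative))
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` mutually exclusive, jointly exhaustive folds
#' of near-equal size, preserving the class balance: within each class the
#' members are dealt evenly across folds, and per-class remainders go to the
#' currently smallest folds, so overall fold sizes differ by at most one and
#' each fold's positive fraction is within one sample of the global one.
#'
#' @param labels Binary 0/1 vector.
#' @param k Number of folds, `>= 2` and at most the minority-class count.
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold indices in `1..k`, with attribute `"k"`.
#' @examples
#' f <- stratified_folds(rep(c(0, 1), c(8, 2)), k = 2, seed = 1)
#' table(f)
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  stopifnot(all(labels %in% c(0, 1)), k >= 2)
  n <- length(labels)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k)) {
    stop("each class must have at least `k` members", call. = FALSE)
  }
  fold <- integer(n)
  with_seed(seed, {
    fold_sizes <- integer(k)
    for (cls in c(1, 0)) {        # minority (positives) dealt first
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      base <- m %/% k
      rem <- m %% k
      # folds ordered smallest-first (ties -> lowest index) receive extras
      ord <- order(fold_sizes, seq_len(k))
      per_fold <- rep(base, k)
      if (rem > 0) per_fold[ord[seq_len(rem)]] <- base + 1L
      pos <- 1L
      for (f in seq_len(k)) {
        take <- per_fold[f]
        if (take > 0) {
          fold[idx[pos:(pos + take - 1L)]] <- f
          pos <- pos + take
        }
      }
      fold_sizes <- fold_sizes + per_fold
    }
  })
  structure(fold, k = as.integer(k))
}

#' Stratified train/test split
#'
#' @param dataset A [pph_dataset()].
#' @param test_fraction Fraction of samples held out, in (0,1). Default 0.3.
#' @param seed Integer seed.
#' @return A list with `train` and `test` datasets plus the integer index
#'   vectors `train_idx` and `test_idx` (disjoint, jointly exhaustive).
#' @export
stratified_split <- function(dataset, test_fraction = 0.3, seed = 1) {
  stopifnot(inherits(dataset, "pph_dataset"))
  stopifnot_scalar_prob(test_fraction, "test_fraction")
  labels <- dataset$labels
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      n_test <- round(length(idx) * test_fraction)
      test_idx <- c(test_idx, idx[sample.int(length(idx), n_test)])
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  list(train = dataset[train_idx, ], test = dataset[test_idx, ],
       train_idx = train_idx, test_idx = test_idx)
}
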