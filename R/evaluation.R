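## Cross-validated classification accuracy of an attribute subset: the
## external yardstick a selected feature set is judged by.

# Stratified fold assignment: within each class, samples are shuffled and
# dealt to folds round-robin, so every fold's class mix tracks the table's.
.stratifiedFolds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated accuracy of an attribute subset
#'
#' Estimates the classification accuracy carried by an attribute subset with
#' stratified k-fold cross-validation and two fixed classifiers: a
#' linear-kernel support vector machine (cost 1) and a k-nearest-neighbour
#' vote (Euclidean distance, majority vote, `knnK` neighbours, 3 by
#' default). Accuracy is the pooled percent of correctly classified held-out
#' samples over all folds, reported to 2 decimals. Fold assignment (and KNN
#' distance-tie breaking) is seeded by the configuration, so repeated calls
#' with the same inputs are identical; the caller's RNG state is restored.
#'
#' If the smallest class has fewer members than `cvFolds`, the fold count is
#' reduced to that size with a warning so every fold's training set still
#' sees every class.
#'
#' @param table a normalized [DecisionTable-class].
#' @param subset non-empty character (or integer) vector of attributes to
#'   restrict the classifiers to.
#' @param config a [selectionConfig()]; `cvFolds`, `knnK` and `seed` are
#'   used.
#' @return A list of class `"rumEval"`: `subset`, `accuracySVM`,
#'   `accuracyKNN` (percent), `folds`, `seed`, and the fixed classifier
#'   settings (`svmCost`, `knnDistance`, `knnVote`).
#' @export
#' @examples
#' tab <- syntheticDecisionTable(nSamples = 40, nNoise = 0,
#'                               effectSize = 0.9, noiseSd = 0.02, seed = 1)
#' evaluateSubset(tab, c("inf1", "inf2"), selectionConfig())
evaluateSubset <- function(table, subset, config = selectionConfig()) {
  stopifnot(is(table, "DecisionTable"), inherits(config, "rumConfig"))
  if (is.numeric(subset)) subset <- attributeNames(table)[subset]
  if (!length(subset)) stop("subset must be non-empty")
  if (!all(subset %in% attributeNames(table))) {
    stop("unknown attribute(s): ",
         paste(setdiff(subset, attributeNames(table)), collapse = ", "))
  }
  x <- attributeValues(table)[, subset, drop = FALSE]
  y <- decisionLabels(table)
  k <- config$cvFolds
  minClass <- min(tabulate(y, nlevels(y)))
  if (minClass < k) {
    warning("reducing folds from ", k, " to ", minClass,
            " so every training fold contains every class")
    k <- minClass
  }

  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)

  folds <- .stratifiedFolds(y, k)
  predSVM <- predKNN <- factor(rep(NA, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                      kernel = "linear", cost = 1, scale = FALSE)
    predSVM[test] <- stats::predict(fit, x[test, , drop = FALSE])
    predKNN[test] <- class::knn(x[!test, , drop = FALSE],
                                x[test, , drop = FALSE],
                                y[!test], k = config$knnK)
  }
  structure(list(
    subset = subset,
    accuracySVM = round(100 * mean(predSVM == y), 2),
    accuracyKNN = round(100 * mean(predKNN == y), 2),
    folds = k,
    knnK = config$knnK,
    seed = config$seed,
    svmCost = 1,
    knnDistance = "euclidean",
    knnVote = "majority"
  ), class = "rumEval")
}

#' @export
print.rumEval <- function(x, ...) {
  cat("Cross-validated accuracy (", x$folds, "-fold, seed ", x$seed, ")\n",
      sep = "")
  cat("  subset:", paste(x$subset, collapse = ", "), "\n")
  cat(sprintf("  linear SVM: %.2f%%   %dNN: %.2f%%\n",
              x$accuracySVM, x$knnK, x$accuracyKNN))
  invisible(x)
}
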