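## Greedy variable-precision attribute reduction driven by the
## conditional-entropy significance, and the (alpha, beta) grid sweep.

#' Select a feature subset by greedy variable-precision reduction
#'
#' Starting from the empty subset, repeatedly adds the candidate attribute
#' with the largest significance (the conditional-entropy drop it buys,
#' ties broken by the smallest attribute index) until the variable-precision
#' stopping rule is met: the conditional entropy of the rough decision given
#' the selected subset is within `beta` bits of the entropy given the full
#' attribute set. The rough decision is computed once from the full
#' attribute set at the configured radius and held fixed while candidate
#' subsets vary.
#'
#' If the tolerance is already met by the empty subset the search selects
#' nothing and warns (`beta` is vacuously large for the table). If no
#' remaining candidate has positive significance while the tolerance is
#' still unmet — possible on noisy data — the search stops, warns, and flags
#' the trace as not converged rather than looping.
#'
#' @param table a normalized [DecisionTable-class].
#' @param config a [selectionConfig()]; `alpha` and `beta` are used here.
#' @param prune logical; after the forward pass, drop (scanning in reverse
#'   selection order) any attribute whose removal keeps the subset within
#'   the `beta` tolerance. Off by default: the forward pass already adds
#'   only attributes that were necessary when chosen.
#' @return A [ReductTrace-class]. Deterministic: the selection itself uses
#'   no randomness.
#' @export
#' @examples
#' tab <- syntheticDecisionTable(nSamples = 40, nInformative = 2,
#'                               nRedundant = 1, nNoise = 2, seed = 7)
#' selectFeatures(tab, selectionConfig(alpha = 0.1, beta = 0.25))
selectFeatures <- function(table, config = selectionConfig(), prune = FALSE) {
  stopifnot(is(table, "DecisionTable"), inherits(config, "rumConfig"))
  if (!isNormalized(table)) {
    stop("table must be normalized first (see normalizeTable)")
  }
  alpha <- config$alpha
  beta <- config$beta
  labels <- decisionLabels(table)
  simFull <- fuzzySimilarity(table, alpha = alpha, thresholded = FALSE)
  rd <- roughDecision(simFull, labels)
  baseline <- .subsetEntropy(table, attributeNames(table), rd, alpha)

  red <- character()
  eCur <- .subsetEntropy(table, character(), rd, alpha)
  steps <- data.frame(attribute = character(), significance = numeric(),
                      entropy = numeric(), stringsAsFactors = FALSE)
  converged <- TRUE

  if (eCur - baseline <= beta) {
    warning("beta tolerance already met by the empty subset; ",
            "no attribute selected")
  } else {
    repeat {
      cand <- setdiff(attributeNames(table), red)
      if (!length(cand)) {
        converged <- FALSE
        break
      }
      ents <- vapply(cand, function(r) {
        .subsetEntropy(table, c(red, r), rd, alpha)
      }, numeric(1L))
      sig <- eCur - ents
      best <- which.max(sig)  # first max: smallest-index tie-break
      if (sig[best] <= 1e-12) {
        warning("no candidate has positive significance; stopping with ",
                length(red), " attribute(s) and tolerance unmet")
        converged <- FALSE
        break
      }
      red <- c(red, cand[best])
      eCur <- ents[best]
      steps <- rbind(steps, data.frame(
        attribute = cand[best], significance = unname(sig[best]),
        entropy = unname(eCur), stringsAsFactors = FALSE))
      if (eCur - baseline <= beta) break
    }
  }

  if (prune && length(red) > 1L) {
    for (b in rev(red)) {
      rest <- setdiff(red, b)
      if (length(rest) &&
          .subsetEntropy(table, rest, rd, alpha) - baseline <= beta) {
        red <- rest
      }
    }
  }

  new("ReductTrace", selected = red, steps = steps,
      baselineEntropy = baseline, alpha = alpha, beta = beta,
      converged = converged)
}

#' Sweep the (alpha, beta) parameter grid
#'
#' Runs [selectFeatures()] followed by [evaluateSubset()] at every point of
#' the grid `{0, gridStep, ..., 0.5}^2` of radius and tolerance values and
#' collects one row per combination. Rows whose selection is empty carry
#' `NA` accuracies. Deterministic given the configuration seed.
#'
#' @param table a normalized [DecisionTable-class].
#' @param config a [selectionConfig()]; `gridStep`, `cvFolds`, `knnK` and
#'   `seed` are used, `alpha`/`beta` are overridden by the grid.
#' @param evaluate logical; set `FALSE` to skip the cross-validated
#'   classification and only record subset sizes (faster exploration).
#' @return A data.frame with columns `alpha`, `beta`, `size`, `selected`
#'   (comma-separated attribute names), `accuracySVM`, `accuracyKNN`
#'   (percent).
#' @export
parameterSweep <- function(table, config = selectionConfig(),
                           evaluate = TRUE) {
  step <- config$gridStep
  nSteps <- 0.5 / step
  if (abs(nSteps - round(nSteps)) > 1e-9) {
    stop("gridStep must divide the [0, 0.5] range exactly")
  }
  values <- round(seq(0, 0.5, by = step), 10)
  grid <- expand.grid(beta = values, alpha = values)[, c("alpha", "beta")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- selectionConfig(alpha = grid$alpha[i], beta = grid$beta[i],
                           gridStep = step, cvFolds = config$cvFolds,
                           knnK = config$knnK, seed = config$seed)
    trace <- suppressWarnings(selectFeatures(table, cfg))
    sel <- selectedAttributes(trace)
    acc <- c(svm = NA_real_, knn = NA_real_)
    if (evaluate && length(sel)) {
      ev <- suppressWarnings(evaluateSubset(table, sel, cfg))
      acc <- c(svm = ev$accuracySVM, knn = ev$accuracyKNN)
    }
    data.frame(alpha = grid$alpha[i], beta = grid$beta[i],
               size = length(sel), selected = paste(sel, collapse = ","),
               accuracySVM = acc[["svm"]], accuracyKNN = acc[["knn"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pick the preferred row of a parameter sweep
#'
#' The sweep reports every (alpha, beta) combination and leaves the final
#' choice open; this helper applies one reasonable, deterministic rule,
#' mirroring the goal of a smaller feature subset with higher accuracy:
#' maximise SVM accuracy, then prefer the smallest subset, then the largest
#' radius (strongest noise filtering), then the largest tolerance
#' (strongest parsimony). Rows with empty selections are ignored.
#'
#' @param sweep a data.frame from [parameterSweep()] (with evaluation).
#' @return The single chosen row of `sweep`.
#' @export
bestSweepRow <- function(sweep) {
  rows <- sweep[!is.na(sweep$accuracySVM) & sweep$size > 0, ]
  if (!nrow(rows)) stop("sweep contains no evaluated non-empty selection")
  rows <- rows[order(-rows$accuracySVM, rows$size,
                     -rows$alpha, -rows$beta), ]
  rows[1L, ]
}
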