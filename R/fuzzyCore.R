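## Fuzzy similarity relations, neighborhood granules, the rough-decision
## membership matrix, and the soft-inclusion cardinality they are compared
## with.  These are the primitives every entropy in the package is built from.

# n x n similarity for one normalized attribute column: complement of the
# absolute difference, zeroed where the difference exceeds 1 - alpha.
.attrSimilarity <- function(col, alpha) {
  d <- abs(outer(col, col, "-"))
  s <- 1 - d
  s[d > 1 - alpha] <- 0
  s
}

#' Fuzzy similarity relation over an attribute subset
#'
#' Computes the fuzzy similarity relation `R_B` of all sample pairs under the
#' attribute subset `B`. Per attribute, the similarity of two samples at
#' absolute value difference `d` is `1 - d` when `d <= 1 - alpha`, else 0;
#' the per-attribute relations are aggregated by the pointwise minimum
#' (the min t-norm); and when `thresholded = TRUE` (the default) aggregate
#' entries below the radius `alpha` are zeroed, which is the cut that turns
#' relation rows into fuzzy neighborhood granules. `thresholded = FALSE`
#' skips that final cut and is what the rough-decision matrix is built from.
#'
#' @param table a normalized [DecisionTable-class].
#' @param attributes character or integer subset of attributes (`B`); the
#'   full set by default. Must be non-empty.
#' @param alpha fuzzy neighborhood radius in [0, 1).
#' @param thresholded logical; apply the final radius cut (default `TRUE`).
#' @return A [FuzzySimilarity-class]: symmetric, unit diagonal, and (when
#'   thresholded) every off-diagonal entry either 0 or `>= alpha`.
#' @export
#' @examples
#' tab <- normalizeTable(DecisionTable(cbind(a = c(0, 0.3, 1)), c("x","y","x")))
#' similarityValues(fuzzySimilarity(tab, alpha = 0.1))
fuzzySimilarity <- function(table, attributes = attributeNames(table),
                            alpha = 0, thresholded = TRUE) {
  stopifnot(is(table, "DecisionTable"))
  if (!isNormalized(table)) {
    stop("table must be normalized first (see normalizeTable)")
  }
  if (is.numeric(attributes)) attributes <- attributeNames(table)[attributes]
  if (!length(attributes)) {
    stop("attribute subset must be non-empty; use universalGranules() for B = {}")
  }
  if (!all(attributes %in% attributeNames(table))) {
    stop("unknown attribute(s): ",
         paste(setdiff(attributes, attributeNames(table)), collapse = ", "))
  }
  v <- table@values
  sim <- .attrSimilarity(v[, attributes[1L]], alpha)
  for (b in attributes[-1L]) {
    sim <- pmin(sim, .attrSimilarity(v[, b], alpha))
  }
  if (thresholded) sim[sim < alpha] <- 0
  diag(sim) <- 1
  new("FuzzySimilarity", values = sim, attributes = as.character(attributes),
      alpha = alpha, thresholded = thresholded)
}

#' Fuzzy neighborhood granules of a similarity relation
#'
#' Row `i` of a (radius-thresholded) similarity relation is the fuzzy
#' neighborhood granule of sample `i`; its cardinality is the number of
#' nonzero memberships. Granules shrink (entrywise) as `alpha` grows, so
#' cardinalities are non-increasing in the radius.
#'
#' @param sim a [FuzzySimilarity-class]. If the radius cut has not been
#'   applied yet, it is applied here.
#' @return A [GranuleSet-class].
#' @export
#' @examples
#' tab <- normalizeTable(DecisionTable(cbind(a = c(0, 0.3, 1)), c("x","y","x")))
#' granuleCardinalities(neighborhoodGranules(fuzzySimilarity(tab, alpha = 0.1)))
neighborhoodGranules <- function(sim) {
  stopifnot(is(sim, "FuzzySimilarity"))
  g <- sim@values
  if (!sim@thresholded) g[g < sim@alpha] <- 0
  diag(g) <- 1
  new("GranuleSet", granules = g,
      cardinalities = as.integer(rowSums(g > 0)),
      alpha = sim@alpha)
}

# The granule set of the empty attribute subset: the indiscernibility
# relation that relates everything, i.e. every granule is the whole universe
# with membership 1.  Gives the greedy search a well-defined starting point.
universalGranules <- function(n) {
  new("GranuleSet", granules = matrix(1, n, n),
      cardinalities = rep(n, n), alpha = 0)
}

#' Rough decision: graded class membership from similarity mass
#'
#' For each sample, its membership in decision class `D_j` is the sum of its
#' fuzzy similarities to the members of `D_j` divided by the sum of its
#' similarities to all samples. The self-similarity of 1 guarantees a
#' positive denominator, and the class sums partition it, so every row sums
#' to 1. The relation passed in should be computed over the *full* attribute
#' set without the final radius cut ([fuzzySimilarity()] with
#' `thresholded = FALSE`): the rough decision is a fixed reference that
#' candidate attribute subsets are scored against, not itself granulated.
#'
#' @param sim a [FuzzySimilarity-class] over the full attribute set.
#' @param labels factor (or vector) of decision classes, one per sample.
#' @return A [RoughDecision-class] with one column per class, classes ordered
#'   by first appearance in `labels`.
#' @export
#' @examples
#' ex <- exampleDecisionSystem()
#' round(membershipMatrix(roughDecision(ex$similarity, ex$labels)), 4)
roughDecision <- function(sim, labels) {
  stopifnot(is(sim, "FuzzySimilarity"))
  if (!is.factor(labels)) {
    labels <- factor(labels, levels = unique(as.character(labels)))
  }
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("at least 2 decision classes are required")
  s <- sim@values
  if (nrow(s) != length(labels)) stop("labels length must match the relation")
  classMass <- vapply(levels(labels),
                      function(cl) rowSums(s[, labels == cl, drop = FALSE]),
                      numeric(nrow(s)))
  rd <- classMass / rowSums(classMass)
  new("RoughDecision", values = unname(rd), classes = levels(labels))
}

#' Soft-inclusion cardinality of one fuzzy set in another
#'
#' `softCardinality(S, T)` counts the objects with *nonzero* membership in
#' `S` whose membership in `S` does not exceed their membership in `T` — the
#' cardinality written `|S n T|` throughout the package. Ties count; objects
#' absent from `S` (membership 0) never count, whatever their `T` membership.
#' The count is asymmetric in its arguments.
#'
#' @param S,T numeric membership vectors of equal length, entries in [0, 1].
#' @return A non-negative integer count.
#' @export
#' @examples
#' ex <- exampleFuzzySets()
#' softCardinality(ex$S, ex$T)  # 4
#' softCardinality(ex$T, ex$S)  # 8
softCardinality <- function(S, T) {
  if (length(S) != length(T)) stop("S and T must have equal length")
  sum(S > 0 & S <= T)
}

#' Granule-decision intersection counts
#'
#' For each sample, the soft-inclusion cardinality of its fuzzy neighborhood
#' granule in the rough-decision column of its *own* class: the number of
#' granule members whose granule membership does not exceed their rough
#' membership in that class. These counts are the denominators of the
#' conditional entropy.
#'
#' @param gset a [GranuleSet-class].
#' @param rd the matching [RoughDecision-class].
#' @param labels decision labels, one per sample.
#' @return Integer vector of length `nSamples`.
#' @seealso [conditionalEntropy()]
#' @export
granuleDecisionCounts <- function(gset, rd, labels) {
  stopifnot(is(gset, "GranuleSet"), is(rd, "RoughDecision"))
  labels <- as.character(labels)
  n <- nrow(gset@granules)
  if (length(labels) != n || nrow(rd@values) != n) {
    stop("granules, rough decision and labels must agree on sample count")
  }
  classCol <- match(labels, rd@classes)
  if (anyNA(classCol)) stop("labels contain classes absent from the rough decision")
  vapply(seq_len(n), function(i) {
    softCardinality(gset@granules[i, ], rd@values[, classCol[i]])
  }, integer(1L))
}
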