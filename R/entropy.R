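## Rough entropy, joint entropy and the conditional entropy of the rough
## decision — the uncertainty measures that score attribute subsets.  All
## logarithms are base 2; results are in bits.

#' Rough entropy of a granule set
#'
#' The average, over samples, of `log2` of the granule cardinality:
#' `-(1/n) sum_i log2(1 / |[x_i]|)`. Zero when every granule is a singleton
#' (every sample fully discernible), `log2(n)` when every granule is the
#' whole universe.
#'
#' @param gset a [GranuleSet-class].
#' @return Entropy in bits, always >= 0.
#' @export
#' @examples
#' ex <- exampleDecisionSystem()
#' roughEntropy(neighborhoodGranules(ex$similarity))
roughEntropy <- function(gset) {
  stopifnot(is(gset, "GranuleSet"))
  mean(log2(gset@cardinalities))
}

#' Joint rough entropy of two granule sets
#'
#' The average of `log2` of the cardinality of the intersection granules:
#' the intersection of two fuzzy vectors is the entrywise minimum, and its
#' cardinality the count of nonzero entries. With itself it reduces to
#' [roughEntropy()].
#'
#' @param gsetB,gsetC [GranuleSet-class] objects over the same universe.
#' @return Entropy in bits.
#' @export
jointEntropy <- function(gsetB, gsetC) {
  stopifnot(is(gsetB, "GranuleSet"), is(gsetC, "GranuleSet"))
  if (nrow(gsetB@granules) != nrow(gsetC@granules)) {
    stop("granule sets must share the same universe")
  }
  inter <- pmin(gsetB@granules, gsetC@granules)
  mean(log2(rowSums(inter > 0)))
}

#' Joint entropy of a granule set with the rough decision
#'
#' The average of `log2` of the granule-decision intersection counts (the
#' soft-inclusion cardinality of each granule in its sample's own
#' rough-decision column). This is the term the decomposition
#' `conditionalEntropy = roughEntropy - jointDecisionEntropy` subtracts;
#' zero counts are clamped to 1 as in [conditionalEntropy()].
#'
#' @param gset a [GranuleSet-class].
#' @param rd the matching [RoughDecision-class].
#' @param labels decision labels, one per sample.
#' @return Entropy in bits.
#' @export
jointDecisionEntropy <- function(gset, rd, labels) {
  counts <- pmax(granuleDecisionCounts(gset, rd, labels), 1L)
  mean(log2(counts))
}

#' Conditional entropy of the rough decision given an attribute subset
#'
#' The rough uncertainty metric: the average over samples of
#' `log2(|[x_i]_B| / |[x_i]_B n RD_i|)`, where the numerator is the fuzzy
#' neighborhood granule cardinality under the subset and the denominator the
#' soft-inclusion count of the granule in the sample's own rough-decision
#' column. It is zero exactly when every granule is softly included in its
#' own class's rough decision, and it never increases when attributes are
#' added (larger subsets discern at least as well).
#'
#' A zero intersection count can arise on degenerate data (the sample's own
#' membership of 1 exceeding its rough-decision value while no other sample
#' qualifies); the count is then clamped to 1 — the value it would take if
#' only the sample itself counted — with a warning, keeping the term finite.
#'
#' @param gset a [GranuleSet-class] for the attribute subset `B`.
#' @param rd the [RoughDecision-class] computed from the full attribute set.
#' @param labels decision labels, one per sample.
#' @return Conditional entropy in bits, always >= 0.
#' @export
#' @examples
#' ex <- exampleDecisionSystem()
#' gs <- neighborhoodGranules(ex$similarity)
#' rd <- roughDecision(ex$similarity, ex$labels)
#' conditionalEntropy(gs, rd, ex$labels)  # 1.0118
conditionalEntropy <- function(gset, rd, labels) {
  counts <- granuleDecisionCounts(gset, rd, labels)
  if (any(counts == 0L)) {
    warning("zero granule-decision intersection count clamped to 1 for ",
            sum(counts == 0L), " sample(s)")
    counts <- pmax(counts, 1L)
  }
  mean(log2(gset@cardinalities / counts))
}

# Conditional entropy for an attribute subset (possibly empty) of a
# normalized table, against a fixed rough decision.  For the empty subset
# (universal granules) the clamp of zero intersection counts to 1 is the
# defined starting convention, so no warning is raised there.
.subsetEntropy <- function(table, subset, rd, alpha) {
  if (length(subset)) {
    gset <- neighborhoodGranules(fuzzySimilarity(table, subset, alpha))
    return(conditionalEntropy(gset, rd, decisionLabels(table)))
  }
  gset <- universalGranules(nSamples(table))
  counts <- pmax(granuleDecisionCounts(gset, rd, decisionLabels(table)), 1L)
  mean(log2(gset@cardinalities / counts))
}

#' Significance of a candidate attribute
#'
#' The conditional-entropy drop achieved by adding `candidate` to the subset
#' `current`:
#' `SIG(r, red, D) = E(RD | red) - E(RD | red u {r})`.
#' With `mode = "remove"` the removal form is computed instead, the drop the
#' attribute's presence contributes to `current`:
#' `SIG(a, A, D) = E(RD | A - {a}) - E(RD | A)`.
#' Non-negative up to floating error (adding attributes never increases the
#' conditional entropy), and exactly zero for an attribute whose addition or
#' removal leaves all granules unchanged — e.g. a duplicate.
#'
#' @param candidate a single attribute identifier.
#' @param current character vector of attributes; the candidate must be
#'   outside it for `"add"` and inside it for `"remove"`.
#' @param table a normalized [DecisionTable-class].
#' @param rd the [RoughDecision-class] from the full attribute set.
#' @param alpha fuzzy neighborhood radius.
#' @param mode `"add"` (default) or `"remove"`.
#' @return Significance in bits.
#' @export
attributeSignificance <- function(candidate, current, table, rd, alpha,
                                  mode = c("add", "remove")) {
  mode <- match.arg(mode)
  if (is.numeric(candidate)) candidate <- attributeNames(table)[candidate]
  if (is.numeric(current)) current <- attributeNames(table)[current]
  if (mode == "add") {
    if (candidate %in% current) stop("candidate is already in the subset")
    .subsetEntropy(table, current, rd, alpha) -
      .subsetEntropy(table, c(current, candidate), rd, alpha)
  } else {
    if (!candidate %in% current) stop("candidate is not in the subset")
    .subsetEntropy(table, setdiff(current, candidate), rd, alpha) -
      .subsetEntropy(table, current, rd, alpha)
  }
}
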