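#' @import methods
NULL

#' Decision table: samples described by continuous attributes plus a class label
#'
#' The central data container: a numeric samples x attributes matrix together
#' with a categorical decision (class) label per sample.  All similarity,
#' granule and entropy computations assume the attribute values have been
#' min-max normalized into [0, 1]; use [normalizeTable()] after construction
#' or [readDecisionTable()] which leaves values raw and records that fact in
#' the `normalized` slot.
#'
#' @slot values numeric matrix, `n_samples x n_attributes`.
#' @slot labels factor of length `n_samples`; levels ordered by first
#'   appearance so the rough-decision column order is deterministic.
#' @slot normalized logical; `TRUE` once every column has been min-max scaled
#'   into [0, 1].
#'
#' @seealso [DecisionTable()], [normalizeTable()], [fuzzySimilarity()]
#' @export
setClass("DecisionTable",
  representation(
    values = "matrix",
    labels = "factor",
    normalized = "logical"
  )
)

setValidity("DecisionTable", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) != length(object@labels)) {
    msg <- c(msg, "labels length must equal the number of rows of values")
  }
  if (ncol(v) < 1L) msg <- c(msg, "at least one attribute is required")
  if (anyNA(v)) msg <- c(msg, "missing attribute values are not permitted")
  if (anyNA(object@labels)) msg <- c(msg, "missing labels are not permitted")
  if (nlevels(droplevels(object@labels)) < 2L) {
    msg <- c(msg, "labels must contain at least 2 non-empty classes")
  }
  if (is.null(colnames(v)) || anyDuplicated(colnames(v))) {
    msg <- c(msg, "attribute names must be present and unique")
  }
  if (isTRUE(object@normalized) && length(v) &&
      (min(v) < 0 || max(v) > 1)) {
    msg <- c(msg, "normalized table has values outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Fuzzy similarity relation over sample pairs
#'
#' Stores the `n x n` fuzzy similarity relation `R_B` computed over an
#' attribute subset `B`: per attribute, samples at absolute difference `d` get
#' similarity `1 - d` when `d <= 1 - alpha` and 0 otherwise; attributes are
#' aggregated by the pointwise minimum; and, when `thresholded`, aggregate
#' entries below `alpha` are zeroed (the neighborhood-radius cut that turns
#' relation rows into fuzzy neighborhood granules).
#'
#' @slot values numeric `n x n` matrix with entries in [0, 1]; symmetric with
#'   unit diagonal.
#' @slot attributes character, the attribute subset the relation was computed
#'   over.
#' @slot alpha numeric, the fuzzy neighborhood radius used.
#' @slot thresholded logical; whether the final radius cut has been applied.
#'
#' @seealso [fuzzySimilarity()], [neighborhoodGranules()], [roughDecision()]
#' @export
setClass("FuzzySimilarity",
  representation(
    values = "matrix",
    attributes = "character",
    alpha = "numeric",
    thresholded = "logical"
  )
)

setValidity("FuzzySimilarity", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "similarity matrix must be square")
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    msg <- c(msg, "similarity entries must lie in [0, 1]")
  }
  if (length(v) && any(abs(diag(v) - 1) > 0)) {
    msg <- c(msg, "similarity must be reflexive (unit diagonal)")
  }
  if (length(v) && !isSymmetric(unname(v))) {
    msg <- c(msg, "similarity must be symmetric")
  }
  if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha >= 1) {
    msg <- c(msg, "alpha must be a single value in [0, 1)")
  }
  if (isTRUE(object@thresholded) && length(v)) {
    off <- v[v > 0 & v < object@alpha]
    if (length(off)) msg <- c(msg, "thresholded relation has entries in (0, alpha)")
  }
  if (length(msg)) msg else TRUE
})

#' Fuzzy neighborhood granules of every sample
#'
#' Row `i` holds the fuzzy neighborhood granule of sample `i`: its
#' (radius-thresholded) similarity to every sample. The granule cardinality is
#' the count of nonzero memberships in the row — the number of samples the
#' granule actually contains.
#'
#' @slot granules numeric `n x n` matrix; row `i` is the granule of sample `i`.
#' @slot cardinalities integer vector of nonzero counts per row (each >= 1,
#'   since self-membership is always 1).
#' @slot alpha numeric, the radius the granules were cut at.
#'
#' @seealso [neighborhoodGranules()], [roughEntropy()], [conditionalEntropy()]
#' @export
setClass("GranuleSet",
  representation(
    granules = "matrix",
    cardinalities = "integer",
    alpha = "numeric"
  )
)

setValidity("GranuleSet", function(object) {
  g <- object@granules
  msg <- character()
  if (nrow(g) != length(object@cardinalities)) {
    msg <- c(msg, "one cardinality per granule row is required")
  }
  if (length(g) && any(diag(g) != 1)) {
    msg <- c(msg, "every sample must belong to its own granule with degree 1")
  }
  if (any(object@cardinalities < 1L)) {
    msg <- c(msg, "granule cardinalities must be >= 1")
  }
  if (length(g) && any(g != 0 & g < object@alpha)) {
    msg <- c(msg, "nonzero granule memberships must be >= alpha")
  }
  if (length(msg)) msg else TRUE
})

#' Rough decision membership matrix
#'
#' The `n x r` matrix `RD` assigning each sample a graded membership in every
#' decision class: entry `(i, j)` is the similarity mass sample `i` carries
#' inside class `j` divided by its total similarity mass, so each row sums
#' to 1.
#'
#' @slot values numeric `n x r` matrix of memberships in [0, 1].
#' @slot classes character, the ordered decision class identifiers (columns).
#'
#' @seealso [roughDecision()], [granuleDecisionCounts()]
#' @export
setClass("RoughDecision",
  representation(
    values = "matrix",
    classes = "character"
  )
)

setValidity("RoughDecision", function(object) {
  v <- object@values
  msg <- character()
  if (ncol(v) != length(object@classes)) {
    msg <- c(msg, "one class identifier per column is required")
  }
  if (ncol(v) < 2L) msg <- c(msg, "at least 2 decision classes are required")
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    msg <- c(msg, "memberships must lie in [0, 1]")
  }
  if (length(v) && any(abs(rowSums(v) - 1) > 1e-9)) {
    msg <- c(msg, "membership rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Trace of a greedy variable-precision attribute reduction
#'
#' Records the ordered attributes selected by [selectFeatures()] together with
#' the significance and conditional entropy at each step, the full-set
#' baseline entropy the variable-precision stopping rule compares against,
#' and the parameters used.
#'
#' @slot selected character, the selected attributes in selection order.
#' @slot steps data.frame with one row per selection step: `attribute`,
#'   `significance` (bits), `entropy` (conditional entropy of the rough
#'   decision given the subset so far, bits).
#' @slot baselineEntropy numeric, conditional entropy given the full
#'   attribute set (bits).
#' @slot alpha,beta numeric, the radius and variable-precision tolerance used.
#' @slot converged logical; `FALSE` when the search stopped without meeting
#'   the tolerance (no candidate had positive significance).
#'
#' @seealso [selectFeatures()], [parameterSweep()]
#' @export
setClass("ReductTrace",
  representation(
    selected = "character",
    steps = "data.frame",
    baselineEntropy = "numeric",
    alpha = "numeric",
    beta = "numeric",
    converged = "logical"
  )
)

setValidity("ReductTrace", function(object) {
  msg <- character()
  if (anyDuplicated(object@selected)) {
    msg <- c(msg, "selected attributes must be unique")
  }
  ent <- object@steps$entropy
  if (length(ent) > 1 && any(diff(ent) > 1e-9)) {
    msg <- c(msg, "per-step conditional entropies must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})
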