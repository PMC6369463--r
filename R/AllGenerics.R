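#' Accessors for rumselect classes
#'
#' `attributeValues()` returns the numeric sample x attribute matrix,
#' `decisionLabels()` the class factor, `attributeNames()` the attribute
#' identifiers, `nSamples()`/`nAttributes()` the table dimensions,
#' `isNormalized()` whether min-max scaling has been applied,
#' `similarityValues()` a similarity relation's matrix, `granuleMatrix()` and
#' `granuleCardinalities()` a granule set's rows and nonzero counts,
#' `membershipMatrix()` the rough-decision matrix, and `selectedAttributes()`
#' a reduction trace's chosen attributes.
#'
#' @param x a rumselect S4 object of the matching class.
#' @return The slot contents described above.
#' @name accessors
#' @aliases attributeValues decisionLabels attributeNames nSamples
#'   nAttributes isNormalized similarityValues granuleMatrix
#'   granuleCardinalities membershipMatrix selectedAttributes
#' @examples
#' tab <- syntheticDecisionTable(seed = 1)
#' nSamples(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("attributeValues", function(x) standardGeneric("attributeValues"))
#' @rdname accessors
#' @export
setGeneric("decisionLabels", function(x) standardGeneric("decisionLabels"))
#' @rdname accessors
#' @export
setGeneric("attributeNames", function(x) standardGeneric("attributeNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nAttributes", function(x) standardGeneric("nAttributes"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("granuleMatrix", function(x) standardGeneric("granuleMatrix"))
#' @rdname accessors
#' @export
setGeneric("granuleCardinalities",
           function(x) standardGeneric("granuleCardinalities"))
#' @rdname accessors
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))
#' @rdname accessors
#' @export
setGeneric("selectedAttributes",
           function(x) standardGeneric("selectedAttributes"))

#' @rdname accessors
setMethod("attributeValues", "DecisionTable", function(x) x@values)
#' @rdname accessors
setMethod("decisionLabels", "DecisionTable", function(x) x@labels)
#' @rdname accessors
setMethod("attributeNames", "DecisionTable", function(x) colnames(x@values))
#' @rdname accessors
setMethod("nSamples", "DecisionTable", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nAttributes", "DecisionTable", function(x) ncol(x@values))
#' @rdname accessors
setMethod("isNormalized", "DecisionTable", function(x) x@normalized)
#' @rdname accessors
setMethod("similarityValues", "FuzzySimilarity", function(x) x@values)
#' @rdname accessors
setMethod("granuleMatrix", "GranuleSet", function(x) x@granules)
#' @rdname accessors
setMethod("granuleCardinalities", "GranuleSet", function(x) x@cardinalities)
#' @rdname accessors
setMethod("membershipMatrix", "RoughDecision", function(x) x@values)
#' @rdname accessors
setMethod("selectedAttributes", "ReductTrace", function(x) x@selected)

setMethod("show", "DecisionTable", function(object) {
  cat("DecisionTable:", nrow(object@values), "samples x",
      ncol(object@values), "attributes\n")
  cat("  classes:",
      paste(sprintf("%s (%d)", levels(object@labels),
                    tabulate(object@labels, nlevels(object@labels))),
            collapse = ", "), "\n")
  cat("  normalized:", object@normalized, "\n")
})

setMethod("show", "FuzzySimilarity", function(object) {
  cat("FuzzySimilarity over", length(object@attributes), "attribute(s),",
      nrow(object@values), "samples\n")
  cat("  alpha:", object@alpha,
      if (object@thresholded) "(radius cut applied)" else "(no radius cut)",
      "\n")
})

setMethod("show", "GranuleSet", function(object) {
  cat("GranuleSet:", nrow(object@granules), "fuzzy neighborhood granules",
      sprintf("(alpha = %g)\n", object@alpha))
  cat("  cardinalities:",
      paste(utils::head(object@cardinalities, 10L), collapse = ", "),
      if (length(object@cardinalities) > 10L) "...\n" else "\n")
})

setMethod("show", "RoughDecision", function(object) {
  cat("RoughDecision:", nrow(object@values), "samples x",
      ncol(object@values), "classes",
      paste0("(", paste(object@classes, collapse = ", "), ")\n"))
})

setMethod("show", "ReductTrace", function(object) {
  cat("ReductTrace: alpha =", object@alpha, "beta =", object@beta, "\n")
  if (length(object@selected)) {
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
    cat(sprintf("  E(RD|red) = %.4f bits vs baseline E(RD|A) = %.4f bits\n",
                utils::tail(object@steps$entropy, 1L),
                object@baselineEntropy))
  } else {
    cat("  selected: (none)\n")
  }
  if (!object@converged) {
    cat("  note: stopped without meeting the beta tolerance\n")
  }
})
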