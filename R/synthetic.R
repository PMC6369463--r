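## Seeded synthetic decision tables with planted ground truth, plus the two
## small worked fixtures the desk-scale tests are anchored to.

#' Generate a synthetic decision table with planted structure
#'
#' Builds a table whose discriminating attributes are known by construction,
#' so selection and evaluation can be tested without external data.
#' Informative attributes are class-conditional Gaussians whose class means
#' are spaced `effectSize` apart (centred on 0.5) with within-class spread
#' `noiseSd`; redundant attributes are exact duplicates of informative ones
#' (assigned round-robin); noise attributes are uniform on [0, 1] and
#' independent of the class. Labels are balanced across classes. Values are
#' clipped into [0, 1] and then min-max rescaled per column, so the returned
#' table is already normalized.
#'
#' Attribute names encode the ground truth: `inf1, inf2, ...` informative,
#' `dup1.inf1, ...` duplicates (suffix names the parent), `noise1, ...`
#' noise.
#'
#' @param nSamples number of samples (default 60).
#' @param nClasses number of balanced classes (default 2).
#' @param nInformative informative attribute count, >= 1 (default 2).
#' @param nRedundant duplicate attribute count (default 1); requires
#'   `nInformative >= 1`.
#' @param nNoise class-independent uniform attribute count (default 5).
#' @param effectSize class-mean separation in normalized units, > 0
#'   (default 0.6).
#' @param noiseSd within-class standard deviation (default 0.1).
#' @param seed integer RNG seed; generation is reproducible and the caller's
#'   RNG state is restored (default 7).
#' @return A normalized [DecisionTable-class].
#' @export
#' @examples
#' tab <- syntheticDecisionTable(seed = 7)
#' attributeNames(tab)
syntheticDecisionTable <- function(nSamples = 60L, nClasses = 2L,
                                   nInformative = 2L, nRedundant = 1L,
                                   nNoise = 5L, effectSize = 0.6,
                                   noiseSd = 0.1, seed = 7L) {
  stopifnot(nSamples >= 2L * nClasses, nClasses >= 2L, nInformative >= 1L,
            nRedundant >= 0L, nNoise >= 0L, effectSize > 0, noiseSd > 0)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)

  labels <- factor(rep_len(paste0("class", seq_len(nClasses)), nSamples),
                   levels = paste0("class", seq_len(nClasses)))
  means <- 0.5 + (seq_len(nClasses) - (nClasses + 1) / 2) * effectSize
  inf <- vapply(seq_len(nInformative), function(j) {
    stats::rnorm(nSamples, mean = means[as.integer(labels)], sd = noiseSd)
  }, numeric(nSamples))
  inf <- pmin(pmax(inf, 0), 1)
  colnames(inf) <- paste0("inf", seq_len(nInformative))

  cols <- inf
  if (nRedundant > 0L) {
    parent <- rep_len(seq_len(nInformative), nRedundant)
    dup <- inf[, parent, drop = FALSE]
    colnames(dup) <- paste0("dup", seq_len(nRedundant), ".inf", parent)
    cols <- cbind(cols, dup)
  }
  if (nNoise > 0L) {
    noise <- matrix(stats::runif(nSamples * nNoise), nSamples, nNoise,
                    dimnames = list(NULL, paste0("noise", seq_len(nNoise))))
    cols <- cbind(cols, noise)
  }
  suppressWarnings(normalizeTable(DecisionTable(cols, labels)))
}

#' Two ten-sample fuzzy membership vectors for soft-cardinality examples
#'
#' A small fixed pair of fuzzy sets over ten objects, used to illustrate the
#' asymmetry of the soft-inclusion cardinality:
#' `softCardinality(S, T)` is 4 while `softCardinality(T, S)` is 8.
#'
#' @return A list with numeric vectors `S` and `T` (length 10, named
#'   `x1 ... x10`).
#' @export
#' @examples
#' ex <- exampleFuzzySets()
#' softCardinality(ex$S, ex$T)
exampleFuzzySets <- function() {
  nm <- paste0("x", 1:10)
  list(
    S = stats::setNames(c(0.7, 0.4, 0.5, 0.7, 0.8, 0.3, 0.5, 0.1, 0.2, 0.6), nm),
    T = stats::setNames(c(0.5, 0.4, 0.3, 0.6, 0.4, 0.7, 0.4, 0.9, 0.2, 0.3), nm)
  )
}

#' A five-sample worked decision system
#'
#' A fixed 5 x 5 fuzzy similarity relation over samples `x1 ... x5` with two
#' decision classes (`D1 = {x1, x2, x3}`, `D2 = {x4, x5}`) and radius
#' `alpha = 0`. The relation is given directly (the attribute values behind
#' it are immaterial); it is the desk-scale anchor for the rough decision,
#' granule cardinalities, intersection counts and conditional entropy: the
#' rough-decision memberships include 0.7311, 0.7973 and 0.8458, the granule
#' cardinalities are (3, 5, 5, 4, 4), the granule-decision counts
#' (3, 2, 3, 2, 1), and the conditional entropy is 1.0118 bits.
#'
#' @return A list with `similarity` (a [FuzzySimilarity-class], alpha 0) and
#'   `labels` (factor, levels `D1`, `D2`).
#' @export
#' @examples
#' ex <- exampleDecisionSystem()
#' conditionalEntropy(neighborhoodGranules(ex$similarity),
#'                    roughDecision(ex$similarity, ex$labels), ex$labels)
exampleDecisionSystem <- function() {
  m <- matrix(c(
    1,    0.53, 0.7,  0,    0,
    0.53, 1,    0.7,  0.2,  0.62,
    0.7,  0.7,  1,    0.11, 0.5,
    0,    0.2,  0.11, 1,    0.7,
    0,    0.62, 0.5,  0.7,  1
  ), nrow = 5, byrow = TRUE)
  sim <- new("FuzzySimilarity", values = m,
             attributes = "A", alpha = 0, thresholded = TRUE)
  list(similarity = sim,
       labels = factor(c("D1", "D1", "D1", "D2", "D2"),
                       levels = c("D1", "D2")))
}
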