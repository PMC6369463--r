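#' Construct a decision table from a matrix and labels
#'
#' @param values numeric matrix or data.frame, samples in rows and attributes
#'   in columns. Column names are used as attribute identifiers; unnamed
#'   columns are named `a1, a2, ...`.
#' @param labels vector of class labels, one per sample. Converted to a
#'   factor whose levels are ordered by first appearance, which fixes the
#'   column order of the rough-decision matrix.
#' @param normalized logical; set `TRUE` only when every column is already
#'   min-max scaled into [0, 1].
#'
#' @return A [DecisionTable-class] object.
#' @seealso [readDecisionTable()], [normalizeTable()]
#' @export
#' @examples
#' tab <- DecisionTable(matrix(runif(20), 10, 2), rep(c("a", "b"), 5))
#' nAttributes(tab)
DecisionTable <- function(values, labels, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("a", seq_len(ncol(values)))
  }
  if (!is.factor(labels)) {
    labels <- factor(labels, levels = unique(as.character(labels)))
  }
  labels <- droplevels(labels)
  new("DecisionTable", values = values, labels = labels,
      normalized = normalized)
}

#' Read a decision table from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the extension, comma
#' otherwise) with one header row, interprets one named column as the
#' decision label and every other column as a numeric attribute. Values are
#' returned raw — call [normalizeTable()] before any similarity computation.
#'
#' @param path path to the delimited file.
#' @param labelColumn name of the label column.
#' @return An un-normalized [DecisionTable-class]; row order is preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(g1 = 1:4, g2 = 4:1, class = c("t", "n", "t", "n")),
#'           f, row.names = FALSE)
#' readDecisionTable(f, "class")
readDecisionTable <- function(path, labelColumn) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (!labelColumn %in% names(raw)) {
    stop("label column '", labelColumn, "' not found; columns are: ",
         paste(names(raw), collapse = ", "))
  }
  labels <- raw[[labelColumn]]
  attrs <- raw[setdiff(names(raw), labelColumn)]
  if (!ncol(attrs)) stop("no attribute columns beside the label column")
  values <- matrix(NA_real_, nrow(attrs), ncol(attrs),
                   dimnames = list(NULL, names(attrs)))
  for (j in seq_along(attrs)) {
    cell <- attrs[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric attribute value '%s' at row %d, column '%s'",
        cell[bad[1L]], bad[1L], names(attrs)[j]))
    }
    values[, j] <- num
  }
  if (length(unique(labels)) < 2L) {
    stop("label column must contain at least 2 distinct classes")
  }
  DecisionTable(values, labels, normalized = FALSE)
}

#' Min-max normalize every attribute column into [0, 1]
#'
#' Each attribute is independently rescaled by
#' `(x - min(x)) / (max(x) - min(x))`, the conventional preprocessing that
#' makes the complement-of-distance fuzzy similarity well defined. A constant
#' (zero-range) column carries no discriminating information and the formula
#' is undefined for it; such columns are mapped to all zeros with a warning.
#'
#' @param table a [DecisionTable-class].
#' @return The table with every value in [0, 1] and `isNormalized()` `TRUE`.
#'   Idempotent, and preserves within-column rank order.
#' @export
#' @examples
#' tab <- DecisionTable(cbind(a = c(2, 4, 6)), c("x", "y", "x"))
#' attributeValues(normalizeTable(tab))[, "a"]
normalizeTable <- function(table) {
  stopifnot(is(table, "DecisionTable"))
  v <- table@values
  rng <- apply(v, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  flat <- span == 0
  if (any(flat)) {
    warning("constant attribute(s) mapped to all zeros: ",
            paste(colnames(v)[flat], collapse = ", "))
    span[flat] <- 1
  }
  v <- sweep(sweep(v, 2L, rng[1L, ], "-"), 2L, span, "/")
  v[, flat] <- 0
  initialize(table, values = v, normalized = TRUE)
}

#' Selection and evaluation parameters
#'
#' Bundles the tunables shared by [selectFeatures()], [parameterSweep()] and
#' [evaluateSubset()]: the fuzzy neighborhood radius `alpha` (memberships
#' below it are cut from granules), the variable-precision tolerance `beta`
#' (the allowed conditional-entropy gap between a reduct and the full
#' attribute set), the sweep grid step, and the cross-validation settings.
#'
#' @param alpha fuzzy neighborhood radius in [0, 1). Default 0.1.
#' @param beta variable-precision tolerance in bits, >= 0. Default 0.25.
#' @param gridStep increment of the (alpha, beta) sweep grid over [0, 0.5].
#'   Default 0.05 (an 11 x 11 grid).
#' @param cvFolds number of stratified cross-validation folds. Default 10.
#' @param knnK neighbour count for the KNN classifier. Default 3.
#' @param seed integer seed for fold assignment. Default 42.
#' @return A validated list of class `"rumConfig"`.
#' @export
#' @examples
#' selectionConfig(alpha = 0.1, beta = 0.25)
selectionConfig <- function(alpha = 0.1, beta = 0.25, gridStep = 0.05,
                            cvFolds = 10L, knnK = 3L, seed = 42L) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 1,
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(gridStep), gridStep > 0,
    cvFolds >= 2L, knnK >= 1L
  )
  structure(list(alpha = alpha, beta = beta, gridStep = gridStep,
                 cvFolds = as.integer(cvFolds), knnK = as.integer(knnK),
                 seed = as.integer(seed)),
            class = "rumConfig")
}

#' Read a selection configuration from a YAML file
#'
#' Accepts keys `alpha`, `beta`, `grid_step`/`gridStep`, `cv_folds`/`cvFolds`,
#' `knn_k`/`knnK`, `rng_seed`/`seed`; missing keys fall back to the
#' [selectionConfig()] defaults.
#'
#' @param path path to a YAML (or flat `key: value`) file.
#' @return A `"rumConfig"` list.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pick <- function(...) {
    for (k in c(...)) if (!is.null(raw[[k]])) return(raw[[k]])
    NULL
  }
  defaults <- selectionConfig()
  selectionConfig(
    alpha = pick("alpha") %||% defaults$alpha,
    beta = pick("beta") %||% defaults$beta,
    gridStep = pick("grid_step", "gridStep") %||% defaults$gridStep,
    cvFolds = pick("cv_folds", "cvFolds") %||% defaults$cvFolds,
    knnK = pick("knn_k", "knnK") %||% defaults$knnK,
    seed = pick("rng_seed", "seed") %||% defaults$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
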