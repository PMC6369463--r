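# Independent scalar-loop oracles.  Deliberately naive (element-wise loops,
# no matrix algebra, no reuse of package internals) so they can stand as
# ground truth for the vectorized implementations.

oracleSoftCardinality <- function(S, T) {
  count <- 0L
  for (i in seq_along(S)) {
    if (S[i] > 0 && S[i] <= T[i]) count <- count + 1L
  }
  count
}

oracleSimilarity <- function(values, subset, alpha) {
  n <- nrow(values)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- Inf
      for (b in subset) {
        d <- abs(values[i, b] - values[j, b])
        sb <- if (d <= 1 - alpha) 1 - d else 0
        if (sb < s) s <- sb
      }
      out[i, j] <- if (s >= alpha) s else 0
    }
  }
  diag(out) <- 1
  out
}

oracleRoughDecision <- function(simValues, labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  n <- nrow(simValues)
  rd <- matrix(0, n, length(classes))
  for (i in seq_len(n)) {
    total <- sum(simValues[i, ])
    for (j in seq_along(classes)) {
      rd[i, j] <- sum(simValues[i, labels == classes[j]]) / total
    }
  }
  list(values = rd, classes = classes)
}

oracleRoughEntropy <- function(granMatrix) {
  acc <- 0
  for (i in seq_len(nrow(granMatrix))) {
    card <- sum(granMatrix[i, ] != 0)
    acc <- acc - log2(1 / card)
  }
  acc / nrow(granMatrix)
}

oracleJointEntropy <- function(gB, gC) {
  acc <- 0
  for (i in seq_len(nrow(gB))) {
    card <- 0L
    for (j in seq_len(ncol(gB))) {
      if (min(gB[i, j], gC[i, j]) != 0) card <- card + 1L
    }
    acc <- acc - log2(1 / card)
  }
  acc / nrow(gB)
}

oracleConditionalEntropy <- function(granMatrix, rdValues, rdClasses, labels) {
  labels <- as.character(labels)
  acc <- 0
  for (i in seq_len(nrow(granMatrix))) {
    card <- sum(granMatrix[i, ] != 0)
    tcol <- rdValues[, match(labels[i], rdClasses)]
    count <- oracleSoftCardinality(granMatrix[i, ], tcol)
    if (count == 0L) count <- 1L
    acc <- acc + log2(card / count)
  }
  acc / nrow(granMatrix)
}

# Random normalized decision table with at least one sample in each of two
# classes; used by the property-style suites.
randomTable <- function(n, p, nClasses = 2L) {
  values <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("a", 1:p)))
  repeat {
    labels <- sample(paste0("c", seq_len(nClasses)), n, replace = TRUE)
    if (length(unique(labels)) >= 2L) break
  }
  DecisionTable(values, labels, normalized = TRUE)
}
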