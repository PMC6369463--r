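# The frozen expected values below were computed with the scalar-loop
# oracles in helper-oracles.R (see the derivations in each block).

exampleParts <- function() {
  ex <- exampleDecisionSystem()
  list(gs = neighborhoodGranules(ex$similarity),
       rd = roughDecision(ex$similarity, ex$labels),
       labels = ex$labels)
}

test_that("rough entropy averages log2 granule cardinalities", {
  n <- 6L
  singletons <- new("GranuleSet", granules = diag(n),
                    cardinalities = rep(1L, n), alpha = 0)
  expect_equal(roughEntropy(singletons), 0)

  full <- new("GranuleSet", granules = matrix(1, n, n),
              cardinalities = rep(n, n), alpha = 0)
  expect_equal(roughEntropy(full), log2(n))

  # worked five-sample system: cardinalities (3, 5, 5, 4, 4)
  p <- exampleParts()
  expect_equal(roughEntropy(p$gs),
               (log2(3) + 2 * log2(5) + 2 * log2(4)) / 5)
  expect_equal(roughEntropy(p$gs), oracleRoughEntropy(granuleMatrix(p$gs)))
  expect_equal(round(roughEntropy(p$gs), 6), 2.045764)
})

test_that("joint entropy uses entrywise-min intersections and matches the oracle", {
  p <- exampleParts()
  expect_equal(jointEntropy(p$gs, p$gs), roughEntropy(p$gs))

  n <- 4L
  singletons <- new("GranuleSet", granules = diag(n),
                    cardinalities = rep(1L, n), alpha = 0)
  expect_equal(jointEntropy(singletons, singletons), 0)

  set.seed(61)
  for (rep in 1:25) {
    tab <- randomTable(sample(4:8, 1), 4)
    alpha <- runif(1, 0, 0.5)
    gB <- neighborhoodGranules(fuzzySimilarity(tab, c("a1", "a2"), alpha))
    gC <- neighborhoodGranules(fuzzySimilarity(tab, c("a3", "a4"), alpha))
    expect_equal(jointEntropy(gB, gC),
                 oracleJointEntropy(granuleMatrix(gB), granuleMatrix(gC)),
                 tolerance = 1e-9)
  }
})

test_that("conditional entropy reproduces the worked example and its terms", {
  p <- exampleParts()
  expect_equal(round(conditionalEntropy(p$gs, p$rd, p$labels), 4), 1.0118)
  # per-sample terms: cardinalities (3,5,5,4,4) over counts (3,2,3,2,1)
  expect_equal(conditionalEntropy(p$gs, p$rd, p$labels),
               (log2(1) + log2(2.5) + log2(5 / 3) + log2(2) + log2(4)) / 5)

  # counts equal to cardinalities give zero uncertainty
  n <- 4L
  gs <- new("GranuleSet", granules = diag(n), cardinalities = rep(1L, n),
            alpha = 0)
  rd <- new("RoughDecision", values = cbind(c(1, 0, 1, 0), c(0, 1, 0, 1)),
            classes = c("a", "b"))
  expect_equal(conditionalEntropy(gs, rd, c("a", "b", "a", "b")), 0)
})

test_that("conditional entropy matches the scalar oracle on random tables", {
  set.seed(71)
  for (rep in 1:30) {
    tab <- randomTable(sample(4:8, 1), sample(2:4, 1))
    alpha <- sample(c(0, 0.1, 0.3, 0.5), 1)
    sub <- sample(attributeNames(tab), sample(nAttributes(tab), 1))
    gs <- neighborhoodGranules(fuzzySimilarity(tab, sub, alpha))
    rd <- roughDecision(fuzzySimilarity(tab, alpha = alpha,
                                        thresholded = FALSE),
                        decisionLabels(tab))
    got <- suppressWarnings(conditionalEntropy(gs, rd, decisionLabels(tab)))
    want <- oracleConditionalEntropy(granuleMatrix(gs), membershipMatrix(rd),
                                     rd@classes, decisionLabels(tab))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the entropy decomposition identity holds on the example and 200 random tables", {
  p <- exampleParts()
  expect_equal(conditionalEntropy(p$gs, p$rd, p$labels),
               roughEntropy(p$gs) - jointDecisionEntropy(p$gs, p$rd, p$labels),
               tolerance = 1e-9)

  set.seed(81)
  for (rep in 1:200) {
    tab <- randomTable(sample(4:8, 1), sample(1:4, 1))
    alpha <- runif(1, 0, 0.5)
    sub <- sample(attributeNames(tab), sample(nAttributes(tab), 1))
    gs <- neighborhoodGranules(fuzzySimilarity(tab, sub, alpha))
    rd <- roughDecision(fuzzySimilarity(tab, alpha = alpha,
                                        thresholded = FALSE),
                        decisionLabels(tab))
    lab <- decisionLabels(tab)
    cond <- suppressWarnings(conditionalEntropy(gs, rd, lab))
    expect_equal(cond, roughEntropy(gs) - jointDecisionEntropy(gs, rd, lab),
                 tolerance = 1e-9)
    # non-negativity in the same sweep
    expect_gte(cond, 0)
  }
})

test_that("a duplicate attribute has exactly zero significance", {
  set.seed(91)
  for (rep in 1:10) {
    tab0 <- randomTable(6, 3)
    v <- attributeValues(tab0)
    v <- cbind(v, dup = v[, "a1"])
    tab <- DecisionTable(v, decisionLabels(tab0), normalized = TRUE)
    alpha <- runif(1, 0, 0.5)
    rd <- roughDecision(fuzzySimilarity(tab, alpha = alpha,
                                        thresholded = FALSE),
                        decisionLabels(tab))
    sig <- suppressWarnings(
      attributeSignificance("dup", c("a1", "a2"), tab, rd, alpha))
    expect_identical(sig, 0)
    sigRm <- suppressWarnings(
      attributeSignificance("dup", c("a1", "a2", "dup"), tab, rd, alpha,
                            mode = "remove"))
    expect_identical(sigRm, 0)
  }
  expect_error(attributeSignificance("a1", "a1", randomTable(4, 2),
                                     NULL, 0), "already in")
})

test_that("a perfectly class-separating attribute has positive significance from scratch", {
  tab <- DecisionTable(
    cbind(sep = c(0, 0.05, 0.1, 0.9, 0.95, 1),
          junk = c(0, 1, 0, 1, 0, 1)),
    rep(c("neg", "pos"), each = 3), normalized = TRUE)
  rd <- roughDecision(fuzzySimilarity(tab, alpha = 0.3, thresholded = FALSE),
                      decisionLabels(tab))
  expect_gt(attributeSignificance("sep", character(0), tab, rd, 0.3), 0)
})

test_that("monotonicity under subset growth has genuine counterexamples (reported)", {
  # Adding attributes provably never grows granules, but the soft-inclusion
  # count is not monotone in the granule, so the conditional entropy can
  # rise when an attribute is added.  This frozen case documents one such
  # counterexample; the seeded scan below quantifies how rare they are.
  v <- matrix(c(0.1780138146, 0.5360537206, 0.5039487120, 0.9450351035,
                0.3413212840, 0.4647137742, 0.0825311816, 0.8601068461,
                0.3956606400, 0.7358993504, 0.1717434060, 0.4547616313,
                0.7702047594, 0.0626499983, 0.8150814951, 0.3011425245,
                0.3646710280, 0.3121127919, 0.0373699649, 0.5188049234),
              5, 4, dimnames = list(NULL, paste0("a", 1:4)))
  tab <- DecisionTable(v, c("c2", "c1", "c1", "c1", "c1"), normalized = TRUE)
  alpha <- 0.5
  rd <- roughDecision(fuzzySimilarity(tab, alpha = alpha, thresholded = FALSE),
                      decisionLabels(tab))
  entropyOf <- function(sub) {
    gs <- neighborhoodGranules(fuzzySimilarity(tab, sub, alpha))
    suppressWarnings(conditionalEntropy(gs, rd, decisionLabels(tab)))
  }
  eN <- entropyOf(c("a1", "a4"))
  eM <- entropyOf(c("a1", "a4", "a2"))
  expect_gt(eM, eN + 0.02)  # a genuine rise, far above float tolerance

  set.seed(101)
  violations <- 0L
  cases <- 0L
  for (rep in 1:200) {
    tab <- randomTable(sample(4:8, 1), sample(2:4, 1))
    alpha <- sample(c(0, 0.1, 0.3, 0.5), 1)
    rd <- roughDecision(fuzzySimilarity(tab, alpha = alpha,
                                        thresholded = FALSE),
                        decisionLabels(tab))
    p <- nAttributes(tab)
    N <- sample(attributeNames(tab), sample(p - 1, 1))
    M <- unique(c(N, sample(attributeNames(tab), sample(p, 1))))
    entropyOf <- function(sub) {
      gs <- neighborhoodGranules(fuzzySimilarity(tab, sub, alpha))
      suppressWarnings(conditionalEntropy(gs, rd, decisionLabels(tab)))
    }
    cases <- cases + 1L
    if (entropyOf(M) > entropyOf(N) + 1e-9) violations <- violations + 1L
  }
  # counterexamples exist but are rare; freeze the seeded scan's outcome so
  # a behavioral change in the entropy surfaces here
  expect_identical(cases, 200L)
  expect_lte(violations, 10L)
  testthat::expect_gte(violations, 1L)
})
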