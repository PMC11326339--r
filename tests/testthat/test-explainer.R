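explainerFixture <- function() {
  memo("explainerFixture", function() {
    tr <- smallTrained()
    pairs <- labelledTrainPairs(tr$split, nMax = 120, seed = 5)
    gates <- trainExplainer(tr$model, tr$split@trainKG, pairs,
                            epochs = 300, seed = 9)
    list(tr = tr, pairs = pairs, gates = gates)
  })
}

test_that("gate probability follows the biased logistic", {
  m <- rnorm(4)
  expect_equal(gateProbability(m, m, numeric(8), bias = 3),
               1 / (1 + exp(-3)))
  expect_equal(gateProbability(m, m, numeric(8), bias = 3), 0.9526,
               tolerance = 1e-4)
  expect_equal(gateProbability(m, m, numeric(8), bias = 0), 0.5)
  p <- gateProbability(m * 100, m * 100, rnorm(8), bias = 0)
  expect_true(p > 0 && p < 1)
  expect_error(gateProbability(m, m, numeric(5)), "length")
})

test_that("mask application substitutes the baseline exactly", {
  m <- c(4, 0); b <- c(0, 4)
  expect_equal(applyMask(m, 1, b), m)
  expect_equal(applyMask(m, 0, b), b)
  expect_equal(applyMask(m, 0.25, b), c(1, 3))
  expect_error(applyMask(m, 1.5, b), "0,1")
})

test_that("masked predictions equal unmasked predictions at initialisation", {
  tr <- smallTrained()
  kg <- tr$split@trainKG
  pairs <- labelledTrainPairs(tr$split, nMax = 60, seed = 5)
  init <- trainExplainer(tr$model, kg, pairs, epochs = 0, seed = 1)
  pMasked <- maskedPredictions(init, tr$model, kg, pairs)
  pOrig <- scorePairs(tr$model, kg, pairs)
  expect_equal(pMasked, pOrig, tolerance = 1e-4)
})

test_that("gate training sparsifies while keeping the multiplier non-negative", {
  fx <- explainerFixture()
  h <- fx$gates@history
  expect_true(all(h$lambda >= 0))
  expect_lt(h$openFraction[length(h$openFraction)], 1)
  expect_true(all(is.finite(h$divergence)))
})

test_that("gate training never touches the predictor weights", {
  tr <- smallTrained()
  kg <- tr$split@trainKG
  before <- sum(tr$model@X) + sum(unlist(tr$model@W)) +
    sum(unlist(tr$model@decoder))
  pairs <- labelledTrainPairs(tr$split, nMax = 40, seed = 5)
  invisible(trainExplainer(tr$model, kg, pairs, epochs = 3, seed = 2))
  after <- sum(tr$model@X) + sum(unlist(tr$model@W)) +
    sum(unlist(tr$model@decoder))
  expect_identical(before, after)
})

test_that("edge importances are bounded with consistent retention flags", {
  fx <- explainerFixture()
  imp <- edgeImportances(fx$gates, fx$tr$model, fx$tr$split@trainKG)
  expect_equal(nrow(imp), edgeCount(fx$tr$split@trainKG))
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_identical(imp$retained, imp$importance > 0.5)
})

test_that("deleting a retained edge perturbs predictions more than a dropped edge", {
  fx <- explainerFixture()
  tr <- fx$tr; kg <- tr$split@trainKG
  imp <- edgeImportances(fx$gates, tr$model, kg)
  pairs <- head(fx$pairs[fx$pairs$label == 1, ], 40)
  p0 <- scorePairs(tr$model, kg, pairs)
  delta <- function(rows) {
    vapply(rows, function(rw) {
      p1 <- scorePairs(tr$model, repurposeKG:::dropEdges(kg, rw), pairs)
      mean(abs(p1 - p0))
    }, numeric(1))
  }
  ordImp <- order(-imp$importance)
  topRows <- head(ordImp[imp$retained[ordImp]], 8)
  lowRows <- head(order(imp$importance), 8)
  expect_gt(stats::median(delta(topRows)), stats::median(delta(lowRows)))
})

test_that("path extraction matches exhaustive enumeration on toy graphs", {
  # drug - gene - disease chain, all retained: exactly one 2-hop path
  kg <- toyKG(indication = FALSE)
  imp <- data.frame(kgEdges(kg), importance = 0.9, retained = TRUE)
  paths <- extractPaths(kg, imp, "drug1", "disease1", maxHops = 3)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$nodes, c("drug1", "gene1", "disease1"))
  expect_equal(paths[[1]]$score, 0.9)
  # nothing retained: clean empty result
  imp$retained <- FALSE
  expect_length(extractPaths(kg, imp, "drug1", "disease1"), 0)
  expect_error(extractPaths(kg, imp, "nope", "disease1"), "absent")

  # <= 8-node toy subgraph vs the DFS oracle
  sim <- simulateKG(nDiseases = 2, nDrugs = 2, nGenes = 2, nPhenotypes = 1,
                    nExposures = 1, nGroups = 2, seed = 3)
  kg2 <- sim$kg
  ed <- kgEdges(kg2)
  # collapse parallel relations as extractPaths does before comparing counts
  dedup <- ed[!duplicated(paste(pmin(ed$head_id, ed$tail_id),
                                pmax(ed$head_id, ed$tail_id))), ]
  imp2 <- data.frame(ed, importance = 0.8, retained = TRUE)
  for (hops in 1:4) {
    got <- extractPaths(kg2, imp2, "drug1", "disease1", maxHops = hops)
    want <- simplePathsOracle(dedup, "drug1", "disease1", hops)
    expect_length(got, length(want))
  }
})

test_that("insertion and deletion endpoints recover the full-graph AUPRC", {
  fx <- explainerFixture()
  tr <- fx$tr
  testNeg <- sampleNegatives(tr$split@test, tr$split@trainKG, seed = 41)
  pairs <- rbind(tr$split@test, testNeg)
  fid <- fidelityMetrics(tr$model, fx$gates, tr$split@trainKG, pairs,
                         kGrid = c(0.2, 1), perturbGrid = 0.05, seed = 6)
  full <- auprc(scorePairs(tr$model, tr$split@trainKG, pairs), pairs$label)
  expect_equal(unname(fid$insertion["K100"]), full, tolerance = 1e-12)
  deletion0 <- fidelityMetrics(tr$model, fx$gates, tr$split@trainKG, pairs,
                               kGrid = 0, perturbGrid = 0.05, seed = 6)
  expect_equal(unname(deletion0$deletion["K0"]), full, tolerance = 1e-12)
  expect_true(all(fid$stability >= -1 & fid$stability <= 1))
})
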