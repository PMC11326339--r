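test_that("signatures indicate 1-hop neighbours in the right blocks", {
  sim <- smallSim(); kg <- sim$kg
  S <- diseaseSignatures(kg)
  nd <- kgNodes(kg)
  expect_equal(ncol(S), sum(nd$type %in% c("gene/protein", "effect/phenotype",
                                           "exposure", "disease")))
  dis <- rownames(S)[1]
  sig <- diseaseSignature(kg, dis)
  nb <- neighborIds(kg, dis)
  nbTyped <- nb[nd$type[match(nb, nd$id)] %in%
                  c("gene/protein", "effect/phenotype", "exposure", "disease")]
  expect_setequal(names(sig)[sig == 1], unique(nbTyped))
  # an isolated disease has the all-zero signature
  kg2 <- makeKG(data.frame(id = c("diseaseX", "geneY"),
                           type = c("disease", "gene/protein")),
                data.frame(head_id = character(), relation = character(),
                           tail_id = character()),
                relationTypes = "disease_gene")
  expect_equal(sum(diseaseSignature(kg2, "diseaseX")), 0)
})

test_that("similarity equals brute-force shared-neighbour counts exhaustively", {
  sim <- simulateKG(nDiseases = 40, nDrugs = 20, nGenes = 100,
                    nPhenotypes = 40, nExposures = 12, nGroups = 4, seed = 13)
  kg <- sim$kg
  expect_lte(nodeCount(kg), 300)
  S <- diseaseSignatures(kg)
  nd <- kgNodes(kg)
  types <- c("gene/protein", "effect/phenotype", "exposure", "disease")
  nb <- function(d) {
    ids <- neighborIds(kg, d)
    unique(ids[nd$type[match(ids, nd$id)] %in% types])
  }
  ds <- rownames(S)
  for (i in seq_along(ds)) for (j in seq_len(i)) {
    expected <- length(intersect(nb(ds[i]), nb(ds[j])))
    if (i == j) expected <- length(nb(ds[i]))
    got <- signatureSimilarity(as.numeric(S[i, ]), as.numeric(S[j, ]))
    expect_identical(unname(got), as.numeric(expected))
    # symmetry
    expect_identical(got, signatureSimilarity(as.numeric(S[j, ]),
                                              as.numeric(S[i, ])))
  }
})

test_that("similarity handles hand-built cases and dimension mismatch", {
  p <- c(1, 1, 1, 0, 0); q <- c(1, 1, 1, 0, 0)
  expect_equal(signatureSimilarity(p, q), 3)
  expect_equal(signatureSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(signatureSimilarity(p, q, normalized = TRUE), 1)
  expect_error(signatureSimilarity(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("top-k retrieval recovers the planted group structure", {
  sim <- smallSim(); kg <- sim$kg
  grp <- sim$ledger$diseaseGroups
  S <- diseaseSignatures(kg)
  for (dis in names(grp)[seq(1, 60, by = 12)]) {
    top <- topKSimilar(kg, dis, k = 5, signatures = S)
    expect_true(all(grp[top$disease] == grp[dis]))
    expect_true(all(diff(top$score) <= 0))  # scores non-increasing in rank
  }
})

test_that("top-k degenerate and boundary cases are deterministic", {
  nodes <- data.frame(id = c("diseaseA", "diseaseB", "gene1"),
                      type = c("disease", "disease", "gene/protein"))
  kg <- makeKG(nodes, data.frame(head_id = "diseaseA",
                                 relation = "disease_gene",
                                 tail_id = "gene1"))
  top <- suppressWarnings(topKSimilar(kg, "diseaseA", k = 1))
  expect_equal(top$disease, "diseaseB")
  # all-zero query: warns, returns lowest-id diseases
  w <- testthat::capture_warnings(topKSimilar(kg, "diseaseB", k = 1))
  expect_match(w, "tie-break|overlap", all = FALSE)
  # k larger than the disease universe: warns and truncates
  w2 <- testthat::capture_warnings(res <- topKSimilar(kg, "diseaseA", k = 10))
  expect_match(w2, "fewer than k", all = FALSE)
  expect_equal(nrow(res), 1)
})

test_that("similarity-weighted aggregation is a convex combination", {
  expect_equal(aggregateSimilar(rbind(c(7, 3)), 2), c(7, 3))
  expect_equal(aggregateSimilar(rbind(c(0, 2), c(2, 0)), c(1, 1)), c(1, 1))
  expect_equal(aggregateSimilar(rbind(c(4, 0), c(0, 4)), c(3, 1)), c(3, 1))
  z <- aggregateSimilar(rbind(c(1, 1), c(2, 2)), c(0, 0))
  expect_equal(as.numeric(z), c(0, 0))
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("gate coefficient follows the shifted exponential", {
  expect_equal(gateCoefficient(0), 0.9)
  expect_equal(gateCoefficient(1), 0.7 * exp(-0.7) + 0.2)
  expect_equal(gateCoefficient(1), 0.5476, tolerance = 1e-4)
  expect_equal(gateCoefficient(1e6), 0.2, tolerance = 1e-12)
  degs <- 0:20
  cs <- gateCoefficient(degs)
  expect_true(all(diff(cs) < 0))                 # strictly decreasing
  expect_true(all(cs > 0.2 & cs <= 0.9))         # range (floor, floor+scale]
  expect_error(gateCoefficient(-1), "non-negative")
})

test_that("augmentation interpolates between own and pooled embeddings", {
  h <- c(2, 0); hs <- c(0, 2)
  expect_equal(augmentEmbedding(h, hs, 0), h)
  expect_equal(augmentEmbedding(h, hs, 1), hs)
  expect_equal(augmentEmbedding(h, hs, 0.5), c(1, 1))
  for (cc in seq(0, 1, by = 0.25)) {
    a <- augmentEmbedding(h, hs, cc)
    expect_true(all(a >= pmin(h, hs) - 1e-12 & a <= pmax(h, hs) + 1e-12))
  }
})

test_that("the pooling operator is row-stochastic over diseases and identity elsewhere", {
  sim <- smallSim(); kg <- sim$kg
  P <- poolingOperator(kg, k = 5)
  rs <- Matrix::rowSums(P)
  expect_equal(unname(as.numeric(rs)), rep(1, nodeCount(kg)), tolerance = 1e-12)
  nd <- kgNodes(kg)
  nonDisease <- which(nd$type != "disease")
  sub <- P[nonDisease, , drop = FALSE]
  expect_equal(sum(sub), length(nonDisease))  # identity rows
  gate <- attr(P, "gate")
  expect_true(all(gate > 0.2 & gate <= 0.9))
})
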