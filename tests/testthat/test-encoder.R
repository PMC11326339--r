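test_that("embedding initialisation is seeded, bounded and centred", {
  kg <- smallSim()$kg
  X1 <- initEmbeddings(kg, d = 8, seed = 42)
  X2 <- initEmbeddings(kg, d = 8, seed = 42)
  expect_identical(X1, X2)
  a <- sqrt(3 / 8)  # Xavier-uniform bound at fan_in = fan_out = d
  expect_true(all(X1 >= -a & X1 <= a))
  # uniform moments: mean of n draws is within 3 standard errors of 0
  big <- initEmbeddings(smallSim()$kg, d = 500, seed = 1)
  n <- length(big)
  aBig <- sqrt(3 / 500)
  se <- (aBig / sqrt(3)) / sqrt(n)  # uniform sd = a/sqrt(3)
  expect_lt(abs(mean(big)), 3 * se)
  expect_error(initEmbeddings(kg, d = 0), "d must be")
})

test_that("message propagation is the relation-specific linear map", {
  H <- matrix(c(1, 1), nrow = 1)
  expect_equal(relationMessages(H, diag(2)), H)
  expect_equal(relationMessages(matrix(0, 1, 2), matrix(1, 2, 2)),
               matrix(0, 1, 2))
  W <- matrix(c(1, 0, 2, 1), 2, 2, byrow = FALSE)  # [[1,2],[0,1]]
  expect_equal(as.numeric(relationMessages(H, t(t(W)))), c(3, 1))
  expect_error(relationMessages(matrix(1, 1, 3), diag(2)), "shape")
})

test_that("aggregation averages neighbour messages, zero when isolated", {
  A <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3), x = 0.5,
                            dims = c(3, 3))
  M <- rbind(c(9, 9), c(1, 1), c(3, 3))
  agg <- aggregateMessages(M, A)
  expect_equal(agg[1, ], c(2, 2))   # mean of [1,1] and [3,3]
  expect_equal(agg[2, ], c(0, 0))   # empty neighbourhood
  single <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  expect_equal(aggregateMessages(M, single)[1, ], M[2, ])
})

test_that("residual update adds aggregates exactly", {
  H <- rbind(c(1, 0))
  expect_equal(updateEmbeddings(H, list()), H)
  expect_equal(updateEmbeddings(H, list(rbind(c(0, 1)), rbind(c(1, 1)))),
               rbind(c(2, 2)))
})

test_that("one layer with identity weights adds the neighbour embedding", {
  nodes <- data.frame(id = c("a", "b"), type = "disease")
  edges <- data.frame(head_id = "a", relation = "disease_disease",
                      tail_id = "b")
  kg <- makeKG(nodes, edges)
  X <- rbind(c(1, 2), c(3, 5))
  W <- list(disease_disease = list(diag(2)))
  H <- encodeGraph(kg, X, W, L = 1)
  expect_equal(H[1, ], X[1, ] + X[2, ])
  expect_equal(H[2, ], X[2, ] + X[1, ])
})

test_that("encoding matches the unrolled oracle on small graphs up to L=3", {
  sim <- simulateKG(nDiseases = 3, nDrugs = 2, nGenes = 3, nPhenotypes = 2,
                    nExposures = 1, nGroups = 2, seed = 5)
  kg <- sim$kg
  expect_lte(nodeCount(kg), 11)
  d <- 4
  X <- initEmbeddings(kg, d = d, seed = 2)
  for (L in 1:3) {
    W <- initRelationParams(relationTypes(kg), d, L, seed = 3)$W
    expect_equal(encodeGraph(kg, X, W, L = L),
                 unrolledEncode(kg, X, W, L), tolerance = 1e-6)
  }
})

test_that("encoding an edgeless graph returns the initial embeddings", {
  nodes <- data.frame(id = c("a", "b", "c"), type = "disease")
  kg <- makeKG(nodes, data.frame(head_id = character(),
                                 relation = character(),
                                 tail_id = character()),
               relationTypes = "disease_disease")
  X <- matrix(rnorm(9), 3, 3)
  W <- list(disease_disease = list(diag(3), diag(3)))
  expect_equal(unname(encodeGraph(kg, X, W, L = 2)), unname(X))
})

test_that("encoding is equivariant under node relabelling", {
  sim <- simulateKG(nDiseases = 5, nDrugs = 3, nGenes = 6, nPhenotypes = 3,
                    nExposures = 2, nGroups = 2, seed = 9)
  kg <- sim$kg
  d <- 4
  X <- initEmbeddings(kg, d = d, seed = 1)
  W <- initRelationParams(relationTypes(kg), d, 2, seed = 4)$W
  H <- encodeGraph(kg, X, W, L = 2)
  perm <- withr::with_seed(3, sample(nodeCount(kg)))
  nd <- kgNodes(kg)[perm, ]
  kg2 <- makeKG(nd, kgEdges(kg), nodeTypes = nodeTypes(kg),
                relationTypes = relationTypes(kg))
  # same ids, permuted rows: reorder X accordingly
  m <- match(kgNodes(kg2)$id, kgNodes(kg)$id)
  H2 <- encodeGraph(kg2, X[m, , drop = FALSE], W, L = 2)
  expect_equal(unname(H2), unname(H[m, , drop = FALSE]), tolerance = 1e-10)
})

test_that("a node's embedding ignores edits outside its L-hop neighbourhood", {
  # chain a-b-c-d-e; editing the far end never reaches node a within L=2
  nodes <- data.frame(id = letters[1:5], type = "disease")
  mkEdges <- function(extra = TRUE) {
    data.frame(head_id = c("a", "b", "c", if (extra) "d"),
               relation = "disease_disease",
               tail_id = c("b", "c", "d", if (extra) "e"))
  }
  d <- 3
  X <- withr::with_seed(8, matrix(rnorm(15), 5, d))
  kgA <- makeKG(nodes, mkEdges(TRUE))
  kgB <- makeKG(nodes, mkEdges(FALSE))
  W <- initRelationParams("disease_disease", d, 2, seed = 6)$W
  HA <- encodeGraph(kgA, X, W, L = 2)
  HB <- encodeGraph(kgB, X, W, L = 2)
  expect_equal(HA[1, ], HB[1, ], tolerance = 1e-12)   # a: unaffected
  expect_false(isTRUE(all.equal(HA[3, ], HB[3, ])))   # c: within 2 hops of d-e
})
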