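test_that("DistMult scoring matches closed forms and is endpoint-symmetric", {
  expect_equal(distmultScore(c(1, 2), c(0, 0), c(3, 4))$p, 0.5)
  r <- distmultScore(c(1, 0), c(1, 1), c(1, 1))
  expect_equal(r$score, 1)
  expect_equal(r$p, 1 / (1 + exp(-1)), tolerance = 1e-6)
  hi <- rnorm(8); hj <- rnorm(8); wr <- rnorm(8)
  expect_equal(distmultScore(hi, wr, hj)$p, distmultScore(hj, wr, hi)$p)
  expect_error(distmultScore(c(1), c(1, 2), c(1, 2)), "mismatch")
})

test_that("binary cross-entropy matches closed forms and is monotone", {
  y <- c(1, 0, 1, 0)
  expect_lt(as.numeric(bceLoss(y, y)), 1e-6)
  expect_equal(as.numeric(bceLoss(rep(0.5, 4), y)), log(2))
  expect_equal(as.numeric(bceLoss(0.9, 1)), -log(0.9))
  # strictly decreasing as p moves toward the label
  ps <- seq(0.05, 0.95, by = 0.1)
  losses <- vapply(ps, function(p) as.numeric(bceLoss(p, 1)), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(bceLoss(0.5, 2), "labels")
})

test_that("pre-training is seeded-deterministic and reduces the loss", {
  sim <- smallSim()
  kg <- sim$kg
  m1 <- pretrainModel(kg, d = 8, L = 2, epochs = 6, seed = 21)
  m2 <- pretrainModel(kg, d = 8, L = 2, epochs = 6, seed = 21)
  expect_identical(m1@history$pretrainLoss, m2@history$pretrainLoss)
  expect_identical(m1@X, m2@X)
  tr <- smallTrained()
  loss <- tr$pretrained@history$pretrainLoss
  expect_lt(mean(tail(loss, 3)), mean(head(loss, 3)))
})

test_that("pre-training learns above-chance all-relation link prediction", {
  tr <- smallTrained()
  kg <- tr$split@trainKG
  ed <- kgEdges(kg)
  pos <- withr::with_seed(2, ed[sample(nrow(ed), 150), ])
  pairs <- data.frame(disease = pos$head_id, drug = pos$tail_id,
                      relation = pos$relation)
  # corrupted counterparts: same relation, random same-type endpoint
  nd <- kgNodes(kg)
  neg <- withr::with_seed(3, {
    data.frame(disease = pos$head_id,
               drug = vapply(pos$tail_id, function(id) {
                 pool <- nd$id[nd$type == nd$type[match(id, nd$id)]]
                 sample(pool, 1)
               }, character(1)),
               relation = pos$relation)
  })
  model <- tr$pretrained
  adjacency <- repurposeKG:::relationAdjacency(kg, model@relations)
  flat <- repurposeKG:::flattenParams(model@X, model@W, model@decoder)
  fw <- repurposeKG:::modelForward(flat, model@relations, model@layers,
                                   adjacency)
  idx <- function(df) data.frame(i = match(df$disease, nd$id),
                                 j = match(df$drug, nd$id),
                                 relation = df$relation)
  pPos <- repurposeKG:::sigmoid(
    repurposeKG:::forwardScores(fw, idx(pairs), model@decoder))
  pNeg <- repurposeKG:::sigmoid(
    repurposeKG:::forwardScores(fw, idx(neg), model@decoder))
  expect_gt(auprc(c(pPos, pNeg), c(rep(1, 150), rep(0, 150))), 0.5)
})

test_that("fine-tuning reinitialises treatment decoders and helps validation", {
  tr <- smallTrained()
  pm <- tr$pretrained; fm <- tr$model
  expect_false(isTRUE(all.equal(pm@decoder$indication,
                                fm@decoder$indication)))
  # fine-tuned model beats the pretrain-only model on the held-out pairs
  evFt <- evaluateSplit(fm, tr$split, negSeed = 77)
  evPre <- evaluateSplit(pm, tr$split, negSeed = 77)
  expect_gt(evFt$auprc, evPre$auprc)
  # and beats the drug-popularity baseline
  neg <- sampleNegatives(tr$split@test, tr$split@trainKG, seed = 77)
  all <- rbind(tr$split@test, neg)
  base <- auprc(degreeBaselineScores(tr$split@trainKG, all), all$label)
  expect_gt(evFt$auprc, base)
})

test_that("checkpoint round-trip reproduces likelihoods bit-identically", {
  tr <- smallTrained()
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(tr$model, f)
  m2 <- loadModel(f)
  pairs <- head(rbind(tr$split@test), 20)
  expect_identical(scorePairs(tr$model, tr$split@trainKG, pairs),
                   scorePairs(m2, tr$split@trainKG, pairs))
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("embedding export round-trips through TSV", {
  tr <- smallTrained()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEmbeddings(tr$model, tr$split@trainKG, f)
  M <- readEmbeddings(f)
  expect_equal(dim(M), c(nodeCount(tr$split@trainKG), tr$model@dim))
  expect_identical(rownames(M), kgNodes(tr$split@trainKG)$id)
  expect_true(all(is.finite(M)))
})

test_that("drug ranking is the descending sort of pair likelihoods", {
  tr <- smallTrained()
  kg <- tr$split@trainKG
  dis <- tr$split@test$disease[1]
  rk <- predictRankedDrugs(tr$model, kg, dis, includeKnown = TRUE)
  expect_true(all(diff(rk$likelihood) <= 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  # agrees with direct pair scoring
  p <- scorePairs(tr$model, kg,
                  data.frame(disease = dis, drug = rk$drug,
                             relation = "indication"))
  expect_equal(rk$likelihood, p)
  # novel-candidate mode removes linked drugs
  linked <- neighborIds(kg, dis, "indication")
  rkNovel <- predictRankedDrugs(tr$model, kg, dis)
  expect_length(intersect(rkNovel$drug, linked), 0)
  expect_error(predictRankedDrugs(tr$model, kg, "no-such-disease"),
               "unknown disease")
})

test_that("planted indications rank above non-indications on average", {
  tr <- smallTrained()
  sim <- tr$sim
  kg <- tr$split@trainKG
  ind <- sim$ledger$indications
  diseases <- unique(tr$split@test$disease[
    tr$split@test$relation == "indication"])[1:5]
  ranksPos <- c(); ranksNeg <- c()
  for (dis in diseases) {
    rk <- predictRankedDrugs(tr$model, kg, dis, includeKnown = TRUE)
    isPlanted <- rk$drug %in% ind$drug[ind$disease == dis]
    if (!any(isPlanted) || all(isPlanted)) next
    ranksPos <- c(ranksPos, rk$rank[isPlanted])
    ranksNeg <- c(ranksNeg, rk$rank[!isPlanted])
  }
  expect_lt(mean(ranksPos), mean(ranksNeg))
})
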