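handRecords <- function() {
  data.frame(
    patient_id = paste0("pt", 1:4),
    diseases = c("d1", "d1;d2", "d2", "d2"),
    drugs = c("rxA", "rxA;rxB", "rxB", "rxA"))
}

test_that("contingency tables match a manual tally and partition the cohort", {
  rec <- handRecords()
  tab <- buildContingency(rec, "d1", "rxA", minDrugPatients = 1)
  expect_equal(tab, c(a = 2, b = 1, c = 0, d = 1))
  expect_equal(sum(tab), nrow(rec))
  tab2 <- buildContingency(rec, "d2", "rxB", minDrugPatients = 1)
  expect_equal(sum(tab2), nrow(rec))
  expect_equal(tab2[["a"]], 2)
  # the >= 10 patient drug filter excludes sparse drugs by default
  expect_error(buildContingency(rec, "d1", "rxA"),
               class = "repurposeKG_filter_error")
  expect_error(buildContingency(rec, "d9", "rxA", minDrugPatients = 1),
               class = "repurposeKG_filter_error")
})

test_that("Fisher log-OR matches hand computation and the enumeration oracle", {
  r <- fisherLogOR(c(a = 10, b = 90, c = 10, d = 890))
  expect_equal(r$oddsRatio, 10 * 890 / (90 * 10), tolerance = 1e-12)
  expect_equal(r$logOR, log(9.888889), tolerance = 1e-4)
  expect_equal(r$logOR, 2.291, tolerance = 1e-3)
  # no association when ad = bc
  expect_equal(fisherLogOR(c(a = 4, b = 2, c = 6, d = 3))$logOR, 0)
  # exact p equals the hypergeometric enumeration on all small-margin tables
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    if (a + b + c + d == 0) next
    got <- fisherLogOR(c(a = a, b = b, c = c, d = d))$pValue
    expect_equal(got, fisherOracle(a, b, c, d), tolerance = 1e-12)
  }
  # a larger-margin spot grid (margins <= 30)
  for (tab in list(c(12, 3, 5, 10), c(1, 14, 9, 6), c(0, 15, 15, 0))) {
    got <- fisherLogOR(c(a = tab[1], b = tab[2], c = tab[3], d = tab[4]))
    expect_equal(got$pValue, fisherOracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("log-OR is antisymmetric under swapping the drug columns", {
  tab <- c(a = 7, b = 13, c = 4, d = 26)
  swapped <- c(a = tab[["c"]], b = tab[["d"]], c = tab[["a"]], d = tab[["b"]])
  expect_equal(fisherLogOR(tab)$logOR, -fisherLogOR(swapped)$logOR)
})

test_that("Bonferroni adjustment caps, scales and flags monotonically", {
  one <- bonferroniAdjust(data.frame(pValue = 0.03))
  expect_equal(one$pAdjusted, 0.03)
  many <- bonferroniAdjust(data.frame(pValue = c(0.01, rep(0.5, 199))))
  expect_equal(many$pAdjusted[1], 1)  # 0.01 * 200 capped at 1
  res <- bonferroniAdjust(data.frame(pValue = c(1e-6, rep(0.9, 999))))
  expect_equal(res$pAdjusted[1], 1e-3)
  expect_true(res$significant[1])
  # lowering alpha never adds significant pairs
  strict <- bonferroniAdjust(data.frame(pValue = res$pValue), alpha = 0.0005)
  expect_true(all(which(strict$significant) %in% which(res$significant)))
})

test_that("the synthetic cohort is seeded, valid and carries planted enrichment", {
  sim <- smallSim()
  r1 <- simulateEMR(sim$ledger, nPatients = 4000, seed = 5)
  r2 <- simulateEMR(sim$ledger, nPatients = 4000, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(nzchar(r1$diseases) & nzchar(r1$drugs)))
  expect_warning(simulateEMR(sim$ledger, nPatients = 50, seed = 1),
                 "unstable")
  # planted indications co-occur with elevated odds
  ind <- head(sim$ledger$indications, 15)
  planted <- data.frame(disease = ind$disease, drug = ind$drug)
  other <- data.frame(disease = sample(planted$disease),
                      drug = rev(planted$drug))
  key <- function(df) paste(df$disease, df$drug)
  other <- other[!key(other) %in% key(sim$ledger$indications), , drop = FALSE]
  enr <- enrichPairs(r1, unique(rbind(planted, other)), minDrugPatients = 1)
  isPlanted <- key(enr) %in% key(planted)
  expect_gt(stats::median(enr$oddsRatio[isPlanted]),
            stats::median(enr$oddsRatio[!isPlanted]))
})

test_that("record CSV round-trips and rejects empty sets", {
  rec <- handRecords()
  f <- withr::local_tempfile(fileext = ".csv")
  writeRecords(rec, f)
  expect_identical(readRecords(f), rec)
  bad <- rec; bad$drugs[2] <- ""
  writeRecords(bad, f)
  expect_error(readRecords(f), ">= 1")
})

test_that("bucket analysis matches a manual two-disease example", {
  # two diseases, four ranked novel drugs each, known log-ORs
  preds <- data.frame(
    disease = rep(c("d1", "d2"), each = 4),
    drug = c("r1", "r2", "r3", "r4", "r1", "r2", "r3", "r4"),
    rank = rep(1:4, 2))
  enr <- data.frame(
    disease = rep(c("d1", "d2"), each = 4),
    drug = c("r1", "r2", "r3", "r4", "r1", "r2", "r3", "r4"),
    logOR = c(2, 1, 0, -1, 4, 3, 2, 1))
  ba <- bucketAnalysis(preds, enr)
  bm <- ba$bucketMeans
  expect_equal(bm$meanLogOR[bm$bucket == "top1"], mean(c(2, 4)))
  expect_equal(bm$meanLogOR[bm$bucket == "top5"],
               mean(c(mean(c(2, 1, 0, -1)), mean(c(4, 3, 2, 1)))))
  # bottom-50%: drugs ranked 3..4 of each disease
  expect_equal(bm$meanLogOR[bm$bucket == "bottom50pct"],
               mean(c(mean(c(0, -1)), mean(c(2, 1)))))
  expect_length(ba$skipped, 0)
  # a disease with no scored candidates is skipped and reported
  preds2 <- rbind(preds, data.frame(disease = "d3", drug = "zz", rank = 1))
  ba2 <- bucketAnalysis(preds2, enr)
  expect_equal(ba2$skipped, "d3")
})
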