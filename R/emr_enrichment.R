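#' @include knowledge_graph.R
NULL

#' Generate a synthetic medical-record cohort with planted enrichment
#'
#' Emulates a de-identified prescription/diagnosis cohort: each patient
#' receives diseases from a skewed prevalence distribution over the
#' knowledge graph's diseases and a baseline set of random prescriptions;
#' drugs that are planted indications of a patient's diseases are
#' co-prescribed with elevated odds (target odds ratio
#' \code{enrichmentStrength}). Every patient ends with at least one drug
#' and one diagnosis.
#'
#' @param ledger synthetic-KG ledger from [simulateKG()] (provides disease
#'   and drug universes and planted indications).
#' @param nPatients cohort size (a warning below 100: unstable tables).
#' @param enrichmentStrength target odds ratio (> 1 plants enrichment).
#' @param baselineRate baseline per-drug prescription probability.
#' @param seed integer seed.
#' @return data.frame (\code{patient_id}, \code{diseases}, \code{drugs})
#'   with semicolon-separated id sets.
#' @export
simulateEMR <- function(ledger, nPatients = 5000, enrichmentStrength = 8,
                        baselineRate = 0.02, seed = 1) {
  if (nPatients < 100) warning("fewer than 100 patients: unstable tables")
  diseases <- names(ledger$diseaseGroups)
  drugs <- names(ledger$drugGroups)
  ind <- ledger$indications
  stopIfNot(!is.null(ind) && nrow(ind) > 0, "ledger has no planted indications")
  indByDisease <- split(ind$drug, ind$disease)
  # elevated probability giving odds ratio ~ enrichmentStrength vs baseline
  oddsBase <- baselineRate / (1 - baselineRate)
  pEnriched <- enrichmentStrength * oddsBase / (1 + enrichmentStrength * oddsBase)
  withSeed(seed, {
    prevalence <- rexp(length(diseases)) ; prevalence <- prevalence / sum(prevalence)
    rows <- vector("list", nPatients)
    for (p in seq_len(nPatients)) {
      nd <- 1 + rpois(1, 0.8)
      ds <- sample(diseases, min(nd, length(diseases)), prob = prevalence)
      rx <- drugs[runif(length(drugs)) < baselineRate]
      planted <- unique(unlist(indByDisease[ds]))
      if (length(planted)) {
        extra <- planted[runif(length(planted)) < pEnriched]
        rx <- union(rx, extra)
      }
      if (!length(rx)) rx <- sample(drugs, 1)
      rows[[p]] <- data.frame(patient_id = paste0("pt", p),
                              diseases = paste(ds, collapse = ";"),
                              drugs = paste(rx, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Read / write patient record CSV files
#'
#' Records are CSV with columns \code{patient_id}, \code{diseases},
#' \code{drugs}; the two set columns are semicolon-separated id lists.
#'
#' @param path CSV file.
#' @return data.frame of records.
#' @export
readRecords <- function(path) {
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  stopIfNot(all(c("patient_id", "diseases", "drugs") %in% names(df)),
            "records need columns patient_id, diseases, drugs")
  ok <- nzchar(df$diseases) & nzchar(df$drugs)
  stopIfNot(all(ok), "every patient needs >= 1 diagnosis and >= 1 drug")
  df
}

#' @rdname readRecords
#' @param records data.frame of records.
#' @export
writeRecords <- function(records, path) {
  write.table(records, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# membership matrices patients x entities
recordSets <- function(records, column) {
  strsplit(records[[column]], ";", fixed = TRUE)
}

#' Patient-level contingency table for one drug-disease pair
#'
#' Counts patients by joint membership: \code{a} with both the diagnosis
#' and the prescription, \code{b} drug without disease, \code{c} disease
#' without drug, \code{d} neither. Entities failing the inclusion filters
#' (disease diagnosed in >= \code{minDiseasePatients} patients, drug
#' prescribed to >= \code{minDrugPatients}) raise a condition.
#'
#' @param records data.frame of patient records.
#' @param disease,drug ids.
#' @param minDiseasePatients,minDrugPatients cohort inclusion filters.
#' @return named integer vector \code{c(a, b, c, d)} summing to the cohort
#'   size.
#' @export
buildContingency <- function(records, disease, drug,
                             minDiseasePatients = 1, minDrugPatients = 10) {
  ds <- recordSets(records, "diseases")
  rx <- recordSets(records, "drugs")
  hasDis <- vapply(ds, function(s) disease %in% s, logical(1))
  hasDrug <- vapply(rx, function(s) drug %in% s, logical(1))
  stopIfNot(sum(hasDis) >= minDiseasePatients,
            paste0("disease ", disease, " fails the >= ",
                   minDiseasePatients, "-patient filter"),
            class = "repurposeKG_filter_error")
  stopIfNot(sum(hasDrug) >= minDrugPatients,
            paste0("drug ", drug, " fails the >= ", minDrugPatients,
                   "-patient filter"),
            class = "repurposeKG_filter_error")
  c(a = sum(hasDis & hasDrug), b = sum(!hasDis & hasDrug),
    c = sum(hasDis & !hasDrug), d = sum(!hasDis & !hasDrug))
}

#' Fisher exact association of a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric tail summation (via
#' \code{stats::fisher.test}); the odds-ratio point estimate is the sample
#' \code{ad/bc}, with the Haldane-Anscombe +0.5 correction applied to all
#' cells when any cell is zero (correction affects the estimate only, not
#' the p-value). Log odds ratio uses the natural log.
#'
#' @param table named vector \code{c(a, b, c, d)} from
#'   [buildContingency()].
#' @return list with \code{oddsRatio}, \code{logOR}, \code{pValue}.
#' @export
fisherLogOR <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  stopIfNot(all(c(a, b, c, d) >= 0), "negative cell count")
  p <- fisher.test(matrix(c(a, c, b, d), 2, 2))$p.value
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  list(oddsRatio = or, logOR = log(or), pValue = p)
}

#' Bonferroni correction with a significance flag
#'
#' Adjusted p = min(1, m p); a pair is significant when the adjusted p is
#' below \code{alpha}.
#'
#' @param results data.frame with a \code{pValue} column.
#' @param alpha significance threshold on the adjusted p.
#' @return \code{results} with \code{pAdjusted} and \code{significant}
#'   columns appended.
#' @export
bonferroniAdjust <- function(results, alpha = 0.005) {
  stopIfNot(nrow(results) >= 1, "no tests to adjust")
  results$pAdjusted <- p.adjust(results$pValue, method = "bonferroni")
  results$significant <- results$pAdjusted < alpha
  results
}

#' Enrichment of many drug-disease pairs in a cohort
#'
#' Builds the contingency table and Fisher log-OR for each requested pair,
#' silently dropping (with a log attribute) pairs whose disease or drug
#' fails the inclusion filters, then applies the Bonferroni correction.
#'
#' @param records patient records.
#' @param pairs data.frame with \code{disease} and \code{drug} columns.
#' @param alpha significance level for the adjusted p.
#' @param minDiseasePatients,minDrugPatients inclusion filters.
#' @return data.frame (\code{disease}, \code{drug}, \code{a..d},
#'   \code{oddsRatio}, \code{logOR}, \code{pValue}, \code{pAdjusted},
#'   \code{significant}); excluded pairs listed in attribute
#'   \code{"excluded"}.
#' @export
enrichPairs <- function(records, pairs, alpha = 0.005,
                        minDiseasePatients = 1, minDrugPatients = 10) {
  ds <- recordSets(records, "diseases")
  rx <- recordSets(records, "drugs")
  allDis <- unique(pairs$disease); allDrug <- unique(pairs$drug)
  disCount <- table(factor(unlist(lapply(ds, unique)), levels = allDis))
  drugCount <- table(factor(unlist(lapply(rx, unique)), levels = allDrug))
  okDis <- names(disCount)[disCount >= minDiseasePatients]
  okDrug <- names(drugCount)[drugCount >= minDrugPatients]
  keep <- pairs$disease %in% okDis & pairs$drug %in% okDrug
  excluded <- pairs[!keep, , drop = FALSE]
  pairs <- pairs[keep, , drop = FALSE]
  stopIfNot(nrow(pairs) > 0, "no pairs survive the inclusion filters")
  n <- length(ds)
  hasDis <- vapply(allDis, function(z)
    vapply(ds, function(s) z %in% s, logical(1)), logical(n))
  hasDrug <- vapply(allDrug, function(z)
    vapply(rx, function(s) z %in% s, logical(1)), logical(n))
  out <- lapply(seq_len(nrow(pairs)), function(ix) {
    hd <- hasDis[, pairs$disease[ix]]; hr <- hasDrug[, pairs$drug[ix]]
    tab <- c(a = sum(hd & hr), b = sum(!hd & hr),
             c = sum(hd & !hr), d = sum(!hd & !hr))
    f <- fisherLogOR(tab)
    data.frame(disease = pairs$disease[ix], drug = pairs$drug[ix],
               a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
               oddsRatio = f$oddsRatio, logOR = f$logOR, pValue = f$pValue,
               stringsAsFactors = FALSE)
  })
  res <- bonferroniAdjust(do.call(rbind, out), alpha = alpha)
  attr(res, "excluded") <- excluded
  attr(res, "logBase") <- "natural"
  res
}

#' Mean log-OR by prediction rank bucket
#'
#' For each disease's ranked novel candidates (drugs already linked to the
#' disease must be excluded upstream), assigns drugs to the buckets top-1,
#' top-5, top-5 percent and bottom-50 percent of the ranking, looks up
#' their log-ORs in the enrichment table, and reports each bucket's mean
#' log-OR across diseases with a 95 percent t-interval. Diseases
#' contributing no scored candidate are skipped and listed.
#'
#' @param rankedPredictions data.frame (\code{disease}, \code{drug},
#'   \code{rank}) with rank 1 = best, per disease.
#' @param enrichment output of [enrichPairs()].
#' @return list with \code{bucketMeans} data.frame (\code{bucket},
#'   \code{meanLogOR}, \code{ci95}, \code{nDiseases}) in the order top-1,
#'   top-5, top-5 percent, bottom-50 percent, and \code{skipped} disease
#'   ids.
#' @export
bucketAnalysis <- function(rankedPredictions, enrichment) {
  key <- paste(enrichment$disease, enrichment$drug)
  lor <- stats::setNames(enrichment$logOR, key)
  buckets <- c("top1", "top5", "top5pct", "bottom50pct")
  perDisease <- list(); skipped <- character(0)
  for (dis in unique(rankedPredictions$disease)) {
    sub <- rankedPredictions[rankedPredictions$disease == dis, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    v <- lor[paste(dis, sub$drug)]
    sub <- sub[!is.na(v), , drop = FALSE]; v <- v[!is.na(v)]
    if (!nrow(sub)) { skipped <- c(skipped, dis); next }
    n <- nrow(sub); v <- unname(v)
    means <- c(
      top1 = v[1],
      top5 = mean(v[seq_len(min(5, n))]),
      top5pct = mean(v[seq_len(max(1, floor(0.05 * n)))]),
      bottom50pct = mean(v[seq(n - floor(n / 2) + 1, n)]))
    perDisease[[dis]] <- means
  }
  stopIfNot(length(perDisease) > 0, "no disease has scored candidates")
  M <- do.call(rbind, perDisease)
  out <- data.frame(
    bucket = buckets,
    meanLogOR = colMeans(M)[buckets],
    ci95 = apply(M[, buckets, drop = FALSE], 2, function(x)
      if (length(x) > 1) qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
      else NA_real_),
    nDiseases = nrow(M), row.names = NULL)
  list(bucketMeans = out, skipped = skipped, perDisease = M)
}
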