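#' @include predictor.R
NULL

#' Area under the precision-recall curve
#'
#' Step-wise (no interpolation): walking down the score-sorted list,
#' AUPRC = sum over positives of precision at each recall increment.
#' Tied scores are grouped so the result does not depend on input order.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  stopIfNot(length(scores) == length(labels), "length mismatch")
  labels <- as.numeric(labels)
  stopIfNot(any(labels == 1) && any(labels == 0),
            "both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))            # threshold groups for ties
  tpCum <- cumsum(y); fpCum <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE) # index of each group's end
  tp <- tpCum[last]; fp <- fpCum[last]
  prec <- tp / (tp + fp)
  nPos <- sum(y)
  rec <- tp / nPos
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic (ties counted half).
#'
#' @inheritParams auprc
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopIfNot(any(labels == 1) && any(labels == 0),
            "both classes must be present")
  r <- rank(scores)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Recall at k
#'
#' Fraction of positives ranked in the top k by score (ties broken by
#' original order after a stable sort).
#'
#' @inheritParams auprc
#' @param k cutoff (>= 1).
#' @return value in [0, 1]; 1 whenever \code{k >= length(scores)}.
#' @export
recallAtK <- function(scores, labels, k) {
  stopIfNot(k >= 1, "k must be >= 1")
  labels <- as.numeric(labels)
  k <- min(k, length(scores))
  top <- order(-scores)[seq_len(k)]
  sum(labels[top]) / sum(labels)
}

evalSplitPairs <- function(model, split, negSeed, pooling = "model") {
  kg <- split@trainKG
  neg <- sampleNegatives(split@test, kg, perPositive = 1L, seed = negSeed)
  all <- rbind(split@test, neg)
  p <- scorePairs(model, kg, all, pooling = pooling)
  list(pairs = all, p = p)
}

#' Evaluate a trained model on a split's test pairs
#'
#' Scores the held-out positives plus fixed seeded 1:1 negatives and
#' reports AUPRC, AUROC and recall at a k grid, overall and per treatment
#' relation.
#'
#' @param model trained \linkS4class{RepurposeModel}.
#' @param split a \linkS4class{KGSplit}.
#' @param negSeed seed for the fixed evaluation negatives.
#' @param kGrid recall cutoffs.
#' @return list of metrics.
#' @export
evaluateSplit <- function(model, split, negSeed = 1,
                          kGrid = c(5, 10, 50)) {
  ev <- evalSplitPairs(model, split, negSeed)
  byRel <- lapply(split(seq_len(nrow(ev$pairs)), ev$pairs$relation),
                  function(ix) {
    y <- ev$pairs$label[ix]
    if (!any(y == 1) || !any(y == 0)) return(NULL)
    list(auprc = auprc(ev$p[ix], y), auroc = auroc(ev$p[ix], y),
         n = length(ix))
  })
  recalls <- vapply(kGrid, function(k)
    recallAtK(ev$p, ev$pairs$label, k), numeric(1))
  list(auprc = auprc(ev$p, ev$pairs$label),
       auroc = auroc(ev$p, ev$pairs$label),
       recallAtK = stats::setNames(recalls, paste0("k", kGrid)),
       perRelation = byRel,
       nPositives = sum(ev$pairs$label == 1),
       nNegatives = sum(ev$pairs$label == 0))
}

#' Benchmark harness over seeded splits
#'
#' Runs the full pipeline (split, pre-train, fine-tune, evaluate) once per
#' seed and reports per-seed metrics with mean and 95 percent t-interval.
#' Evaluation negatives are fixed per split at 1:1 with positives.
#'
#' @param kg the full \linkS4class{KnowledgeGraph}.
#' @param strategy split strategy, see [makeSplit()].
#' @param nSeeds number of seeded repeats.
#' @param baseSeed seeds used are \code{baseSeed + 0:(nSeeds-1)}.
#' @param d,L,pretrainEpochs,finetuneEpochs,pooling model configuration.
#' @param holdoutFraction,diseaseAreaMembers,thinningFraction split
#'   configuration.
#' @param indicationOnly evaluate the indication relation only.
#' @return list with \code{perSeed} data.frame, \code{mean}, \code{ci95}
#'   (half-width; \code{NA} flagged when nSeeds = 1), and the
#'   configuration. Seeds that fail are reported in \code{failures}.
#' @export
runBenchmark <- function(kg, strategy = "random_pair", nSeeds = 5,
                         baseSeed = 1, d = 32, L = 2, pretrainEpochs = 30,
                         finetuneEpochs = 60, pooling = TRUE,
                         holdoutFraction = 0.1, diseaseAreaMembers = NULL,
                         thinningFraction = 0.95, indicationOnly = FALSE) {
  stopIfNot(nSeeds >= 1, "nSeeds must be >= 1")
  rows <- list(); failures <- list()
  for (s in baseSeed + seq_len(nSeeds) - 1) {
    res <- tryCatch({
      sp <- makeSplit(kg, strategy, holdoutFraction = holdoutFraction,
                      diseaseAreaMembers = diseaseAreaMembers,
                      thinningFraction = thinningFraction, seed = s)
      pm <- pretrainModel(sp@trainKG, d = d, L = L,
                          epochs = pretrainEpochs, seed = s)
      fm <- fineTuneModel(pm, sp, epochs = finetuneEpochs,
                          pooling = pooling, seed = s)
      if (indicationOnly) {
        keep <- sp@test$relation == "indication"
        sp@test <- sp@test[keep, , drop = FALSE]
      }
      ev <- evaluateSplit(fm, sp, negSeed = childSeed(s, 9))
      data.frame(seed = s, auprc = ev$auprc, auroc = ev$auroc,
                 validAUPRC = fm@history$bestValidAUPRC)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[as.character(s)]] <- conditionMessage(res)
    else rows[[as.character(s)]] <- res
  }
  perSeed <- do.call(rbind, rows)
  summarise <- function(x) {
    m <- mean(x)
    ci <- if (length(x) > 1) qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
          else NA_real_  # point estimate; CI undefined at one seed
    c(mean = m, ci95 = ci)
  }
  list(perSeed = perSeed,
       auprc = summarise(perSeed$auprc),
       auroc = summarise(perSeed$auroc),
       failures = failures,
       config = list(strategy = strategy, nSeeds = nSeeds, d = d, L = L,
                     pooling = pooling, holdoutFraction = holdoutFraction,
                     negativeConvention = "fixed seeded 1:1 per split"))
}
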