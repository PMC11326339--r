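#' @include knowledge_graph.R
NULL

TREATMENT_RELATIONS <- c("indication", "contraindication", "off_label")

# drop edge rows (by index) from a KG, keeping all nodes
dropEdges <- function(kg, rows) {
  ed <- kg@edges
  if (length(rows)) ed <- ed[-rows, , drop = FALSE]
  rownames(ed) <- NULL
  new("KnowledgeGraph", nodes = kg@nodes, edges = ed,
      nodeTypes = kg@nodeTypes, relationTypes = kg@relationTypes)
}

# orient a treatment edge as (disease, drug)
orientPairs <- function(kg, edgeRows) {
  ed <- kg@edges[edgeRows, , drop = FALSE]
  ty <- kg@nodes$type
  headIsDisease <- ty[ed$head] == "disease"
  data.frame(
    disease = kg@nodes$id[ifelse(headIsDisease, ed$head, ed$tail)],
    drug = kg@nodes$id[ifelse(headIsDisease, ed$tail, ed$head)],
    relation = ed$relation,
    label = 1L,
    stringsAsFactors = FALSE)
}

#' Curate an evaluation split
#'
#' Three strategies mirroring increasingly stringent generalisation tests:
#' \describe{
#'   \item{random_pair}{a fraction of drug--disease treatment edges held
#'     out uniformly at random; held-out diseases typically keep other
#'     treatment edges in training.}
#'   \item{zero_shot_disease}{a random subset of diseases held out with
#'     \emph{all} of their treatment edges moved to the test set, so each
#'     test disease has zero indication/contraindication/off-label edges in
#'     training.}
#'   \item{disease_area}{a named disease set held out with all treatment
#'     edges, and additionally a fraction of those diseases' remaining
#'     (non-treatment) edges deleted from the training graph, emulating
#'     poorly characterised disease areas.}
#' }
#' Holdout counts use \code{max(1, floor(fraction * n))}. A validation set
#' of treatment pairs is carved from the remaining training edges.
#'
#' @param kg a \linkS4class{KnowledgeGraph} containing treatment edges.
#' @param strategy one of \code{"random_pair"}, \code{"zero_shot_disease"},
#'   \code{"disease_area"}.
#' @param holdoutFraction fraction in (0,1): of treatment edges
#'   (random_pair) or of diseases (zero_shot_disease).
#' @param diseaseAreaMembers character disease ids defining the held-out
#'   area (required for \code{disease_area}).
#' @param thinningFraction fraction in [0,1) of held-out diseases' remaining
#'   non-treatment edges removed from training (\code{disease_area} only).
#' @param excludeSimilarCutoff optional (\code{disease_area} only): when
#'   set, training diseases whose shared-neighbour similarity to any
#'   held-out disease reaches the cutoff also lose their treatment edges
#'   from training (they are not evaluated). Off (\code{NULL}) by default;
#'   no reference value exists for the cutoff.
#' @param validFraction fraction of remaining training treatment edges held
#'   out as validation positives.
#' @param treatmentRelations relation labels counted as treatment edges.
#' @param seed integer seed.
#' @return A \linkS4class{KGSplit}.
#' @export
makeSplit <- function(kg, strategy = c("random_pair", "zero_shot_disease",
                                       "disease_area"),
                      holdoutFraction = 0.1, diseaseAreaMembers = NULL,
                      thinningFraction = 0.95, excludeSimilarCutoff = NULL,
                      validFraction = 0.05,
                      treatmentRelations = TREATMENT_RELATIONS, seed = 1) {
  strategy <- match.arg(strategy)
  stopIfNot(holdoutFraction > 0 && holdoutFraction < 1,
            "holdoutFraction must be in (0,1)")
  stopIfNot(thinningFraction >= 0 && thinningFraction < 1,
            "thinningFraction must be in [0,1)")
  treatRows <- which(kg@edges$relation %in% treatmentRelations)
  stopIfNot(length(treatRows) > 0, "kg contains no treatment edges")
  nd <- kg@nodes

  withSeed(seed, {
    if (strategy == "random_pair") {
      nHold <- max(1L, floor(holdoutFraction * length(treatRows)))
      testRows <- sample(treatRows, nHold)
      held <- character(0)
      thinned <- integer(0)
    } else {
      if (strategy == "zero_shot_disease") {
        touched <- unique(c(kg@edges$head[treatRows], kg@edges$tail[treatRows]))
        diseaseIdx <- touched[nd$type[touched] == "disease"]
        nHold <- max(1L, floor(holdoutFraction * length(diseaseIdx)))
        heldIdx <- sample(diseaseIdx, nHold)
      } else {
        stopIfNot(!is.null(diseaseAreaMembers) && length(diseaseAreaMembers) > 0,
                  "disease_area strategy needs diseaseAreaMembers")
        heldIdx <- match(diseaseAreaMembers, nd$id)
        stopIfNot(!anyNA(heldIdx), "disease area member not found in kg")
        stopIfNot(all(nd$type[heldIdx] == "disease"),
                  "disease area members must be disease nodes")
      }
      held <- nd$id[heldIdx]
      touchesHeld <- kg@edges$head %in% heldIdx | kg@edges$tail %in% heldIdx
      testRows <- which(touchesHeld &
                        kg@edges$relation %in% treatmentRelations)
      thinned <- integer(0)
      if (strategy == "disease_area" && thinningFraction > 0) {
        aux <- which(touchesHeld &
                     !(kg@edges$relation %in% treatmentRelations))
        nThin <- floor(thinningFraction * length(aux))
        if (nThin > 0) thinned <- sample(aux, nThin)
      }
      if (strategy == "disease_area" && !is.null(excludeSimilarCutoff)) {
        S <- diseaseSignatures(kg)
        others <- setdiff(rownames(S), held)
        sim <- as.matrix(S[others, , drop = FALSE] %*%
                           Matrix::t(S[held, , drop = FALSE]))
        near <- others[apply(sim, 1, max) >= excludeSimilarCutoff]
        if (length(near)) {
          nearIdx <- match(near, nd$id)
          nearTreat <- which((kg@edges$head %in% nearIdx |
                              kg@edges$tail %in% nearIdx) &
                             kg@edges$relation %in% treatmentRelations)
          thinned <- union(thinned, setdiff(nearTreat, testRows))
        }
      }
    }

    test <- orientPairs(kg, testRows)
    trainKG <- dropEdges(kg, c(testRows, thinned))

    for (r in intersect(treatmentRelations, unique(kg@edges$relation))) {
      stopIfNot(any(trainKG@edges$relation == r),
                paste0("holdout leaves relation '", r, "' empty in train"))
    }

    # validation positives from remaining training treatment edges
    vRows <- which(trainKG@edges$relation %in% treatmentRelations)
    nValid <- max(1L, floor(validFraction * length(vRows)))
    validRows <- sample(vRows, min(nValid, length(vRows)))
    valid <- orientPairs(trainKG, validRows)
    trainKG <- dropEdges(trainKG, validRows)
  })

  new("KGSplit", trainKG = trainKG, valid = valid, test = test,
      strategy = strategy, heldDiseases = held,
      spec = list(holdoutFraction = holdoutFraction,
                  thinningFraction = thinningFraction,
                  excludeSimilarCutoff = excludeSimilarCutoff,
                  validFraction = validFraction,
                  treatmentRelations = treatmentRelations,
                  nThinned = length(if (exists("thinned")) thinned else integer(0)),
                  seed = seed))
}

#' Sample type-consistent negative pairs
#'
#' For each positive (disease, drug, relation) pair, draws
#' \code{perPositive} corrupted pairs by replacing one endpoint (drug and
#' disease endpoints alternate) with a uniformly chosen node of the same
#' type, rejecting corruptions present among the known positives of that
#' relation anywhere in the reference graph.
#'
#' @param pairs data.frame of positive pairs (\code{disease}, \code{drug},
#'   \code{relation}).
#' @param kg reference \linkS4class{KnowledgeGraph} used to filter against
#'   known positives (typically the full, unsplit graph).
#' @param perPositive negatives per positive (>= 1).
#' @param seed integer seed; the same seed reproduces the same negatives.
#' @return data.frame of corrupted pairs with \code{label = 0}.
#' @export
sampleNegatives <- function(pairs, kg, perPositive = 1L, seed = 1) {
  stopIfNot(perPositive >= 1, "perPositive must be >= 1")
  stopIfNot(nrow(pairs) > 0, "no positive pairs given")
  nd <- kg@nodes
  diseases <- nd$id[nd$type == "disease"]
  drugs <- nd$id[nd$type == "drug"]
  known <- kgEdges(kg)
  knownKey <- c(paste(known$head_id, known$relation, known$tail_id, sep = "\r"),
                paste(known$tail_id, known$relation, known$head_id, sep = "\r"))
  out <- vector("list", perPositive * nrow(pairs))
  withSeed(seed, {
    k <- 0L
    for (p in seq_len(nrow(pairs))) {
      for (m in seq_len(perPositive)) {
        corruptDrug <- ((p + m) %% 2L) == 0L
        pool <- if (corruptDrug) drugs else diseases
        found <- FALSE
        for (attempt in seq_len(200L)) {
          cand <- sample(pool, 1L)
          dis <- if (corruptDrug) pairs$disease[p] else cand
          drg <- if (corruptDrug) cand else pairs$drug[p]
          key <- paste(dis, pairs$relation[p], drg, sep = "\r")
          if (!(key %in% knownKey)) { found <- TRUE; break }
        }
        stopIfNot(found,
                  "candidate pool exhausted; use a smaller perPositive")
        k <- k + 1L
        out[[k]] <- data.frame(disease = dis, drug = drg,
                               relation = pairs$relation[p], label = 0L,
                               stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, out)
}

setMethod("show", "KGSplit", function(object) {
  cat("KGSplit [", object@strategy, "]\n", sep = "")
  cat("  train:", edgeCount(object@trainKG), "edges;",
      nrow(object@valid), "valid pairs;", nrow(object@test), "test pairs\n")
  if (length(object@heldDiseases))
    cat("  held-out diseases:", length(object@heldDiseases), "\n")
})
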