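#' @include encoder.R disease_similarity.R splits.R
NULL

#' DistMult likelihood of a relation between two nodes
#'
#' Raw score \eqn{s = \sum_d h_i \odot w_r \odot h_j} (elementwise triple
#' product, symmetric in the two endpoints) mapped through the logistic
#' function: \eqn{p = 1/(1+e^{-s})}.
#'
#' @param hi,hj embedding vectors of the two nodes.
#' @param wr relation decoder vector of the same dimension.
#' @return list with \code{score} and likelihood \code{p}.
#' @export
distmultScore <- function(hi, wr, hj) {
  stopIfNot(length(hi) == length(wr) && length(wr) == length(hj),
            "dimension mismatch")
  s <- sum(hi * wr * hj)
  list(score = s, p = as.numeric(sigmoid(s)))
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of Bernoulli labels under predicted
#' probabilities, with probabilities clipped to \code{[eps, 1-eps]}.
#'
#' @param p predicted probabilities.
#' @param y labels in \{0, 1\}.
#' @param eps clipping constant.
#' @return scalar loss (>= 0) with attribute \code{"terms"}, the per-pair
#'   negative log-likelihoods.
#' @export
bceLoss <- function(p, y, eps = 1e-7) {
  stopIfNot(length(p) == length(y), "length mismatch")
  stopIfNot(all(y %in% c(0, 1)), "labels must be 0/1")
  pc <- clipProb(p, eps)
  terms <- -(y * log(pc) + (1 - y) * log(1 - pc))
  out <- mean(terms)
  attr(out, "terms") <- terms
  out
}

# ---- internal training machinery ------------------------------------------

# add rows into M at (possibly repeated) indices
accumRows <- function(M, idx, rows) {
  agg <- rowsum(rows, group = idx)
  at <- as.integer(rownames(agg))
  M[at, ] <- M[at, , drop = FALSE] + agg
  M
}

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# flatten model trainables to a named list of arrays and back
flattenParams <- function(X, W, decoder) {
  out <- list(X = X)
  for (r in names(W)) for (l in seq_along(W[[r]]))
    out[[paste0("W.", r, ".", l)]] <- W[[r]][[l]]
  for (r in names(decoder)) out[[paste0("dec.", r)]] <- decoder[[r]]
  out
}

unflattenParams <- function(flat, relations, L) {
  W <- lapply(relations, function(r)
    lapply(seq_len(L), function(l) flat[[paste0("W.", r, ".", l)]]))
  names(W) <- relations
  decoder <- lapply(relations, function(r) flat[[paste0("dec.", r)]])
  names(decoder) <- relations
  list(X = flat$X, W = W, decoder = decoder)
}

# forward pass: layers + optional pooling; returns list(layers, H, Hhat)
modelForward <- function(flat, relations, L, adjacency, P = NULL) {
  un <- unflattenParams(flat, relations, L)
  layers <- vector("list", L + 1L)
  layers[[1]] <- un$X
  H <- un$X
  for (l in seq_len(L)) {
    for (r in relations)
      H <- H + as.matrix(adjacency[[r]] %*% (layers[[l]] %*% t(un$W[[r]][[l]])))
    layers[[l + 1L]] <- H
  }
  Hhat <- if (is.null(P)) H else as.matrix(P %*% H)
  list(layers = layers, H = H, Hhat = Hhat, un = un)
}

# score a pair table (integer idx columns i, j; character relation)
forwardScores <- function(fw, pairIdx, decoder) {
  s <- numeric(nrow(pairIdx))
  for (r in unique(pairIdx$relation)) {
    sel <- pairIdx$relation == r
    A <- fw$Hhat[pairIdx$i[sel], , drop = FALSE]
    B <- fw$Hhat[pairIdx$j[sel], , drop = FALSE]
    s[sel] <- as.numeric((A * B) %*% decoder[[r]])
  }
  s
}

# full backward pass for the BCE objective; returns grads for flat params
modelBackward <- function(flat, fw, relations, L, adjacency, P, pairIdx, y) {
  un <- fw$un
  d <- ncol(un$X)
  n <- nrow(un$X)
  s <- forwardScores(fw, pairIdx, un$decoder)
  p <- sigmoid(s)
  g <- (p - y) / length(y)

  Ghat <- matrix(0, n, d)
  grads <- list()
  for (r in relations) grads[[paste0("dec.", r)]] <- numeric(d)
  for (r in unique(pairIdx$relation)) {
    sel <- pairIdx$relation == r
    A <- fw$Hhat[pairIdx$i[sel], , drop = FALSE]
    B <- fw$Hhat[pairIdx$j[sel], , drop = FALSE]
    wr <- un$decoder[[r]]
    gr <- g[sel]
    grads[[paste0("dec.", r)]] <- as.numeric(colSums(gr * A * B))
    Ghat <- accumRows(Ghat, pairIdx$i[sel],
                      gr * sweep(B, 2, wr, "*"))
    Ghat <- accumRows(Ghat, pairIdx$j[sel],
                      gr * sweep(A, 2, wr, "*"))
  }
  G <- if (is.null(P)) Ghat else as.matrix(Matrix::t(P) %*% Ghat)
  for (l in rev(seq_len(L))) {
    Hprev <- fw$layers[[l]]
    Gnew <- G
    for (r in relations) {
      B <- as.matrix(adjacency[[r]] %*% Hprev)
      grads[[paste0("W.", r, ".", l)]] <- crossprod(G, B)
      Gnew <- Gnew + as.matrix(Matrix::t(adjacency[[r]]) %*%
                                 (G %*% un$W[[r]][[l]]))
    }
    G <- Gnew
  }
  grads$X <- G
  list(grads = grads, loss = as.numeric(bceLoss(p, y)), p = p)
}

# fast type-consistent corruption used inside training epochs
corruptPairs <- function(kg, pairIdx, edgeKeys) {
  n <- nrow(pairIdx)
  typeOf <- kg@nodes$type
  out <- pairIdx
  corruptJ <- seq_len(n) %% 2L == 0L
  for (side in c(TRUE, FALSE)) {
    rows <- which(corruptJ == side)
    if (!length(rows)) next
    old <- if (side) pairIdx$j[rows] else pairIdx$i[rows]
    cand <- vapply(old, function(ix) {
      pool <- which(typeOf == typeOf[ix])
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    if (side) out$j[rows] <- cand else out$i[rows] <- cand
  }
  key <- paste(pmin(out$i, out$j), out$relation, pmax(out$i, out$j))
  hit <- key %in% edgeKeys
  if (any(hit)) out <- out[!hit, , drop = FALSE]  # drop accidental positives
  out
}

kgEdgeKeys <- function(kg) {
  ed <- kg@edges
  paste(pmin(ed$head, ed$tail), ed$relation, pmax(ed$head, ed$tail))
}

#' Pre-train a link-prediction model on all relations
#'
#' Optimises the encoder (initial embeddings + per-relation per-layer
#' message weights) and per-relation DistMult decoder vectors on link
#' prediction across every relation type of the graph, treating all
#' relations equally. Every edge is visited each epoch (stochastic
#' minibatches over edges with full-graph message passing); negatives are
#' resampled each epoch by type-consistent endpoint corruption. Disease
#' pooling is deactivated during this phase.
#'
#' @param kg training \linkS4class{KnowledgeGraph}.
#' @param d embedding dimension.
#' @param L message-passing layers.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batchSize pairs per gradient step.
#' @param seed integer seed controlling initialisation and sampling.
#' @param verbose print epoch losses.
#' @return A \linkS4class{RepurposeModel} (pooling inactive).
#' @export
pretrainModel <- function(kg, d = 128, L = 2, epochs = 40, lr = 1e-3,
                          batchSize = 8192, seed = 1, verbose = FALSE) {
  stopIfNot(edgeCount(kg) > 0, "training graph has no edges")
  relations <- relationTypes(kg)
  adjacency <- relationAdjacency(kg, relations)
  X <- initEmbeddings(kg, d, seed = childSeed(seed, 1))
  rp <- initRelationParams(relations, d, L, seed = childSeed(seed, 2))
  flat <- flattenParams(X, rp$W, rp$decoder)
  state <- adamInit(flat)
  ed <- kg@edges
  pos <- data.frame(i = ed$head, j = ed$tail, relation = ed$relation,
                    stringsAsFactors = FALSE)
  edgeKeys <- kgEdgeKeys(kg)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    withSeed(childSeed(seed, 100 + ep), {
      neg <- corruptPairs(kg, pos, edgeKeys)
      pairs <- rbind(pos, neg)
      y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
      ord <- sample.int(nrow(pairs))
    })
    pairs <- pairs[ord, , drop = FALSE]; y <- y[ord]
    batches <- split(seq_len(nrow(pairs)),
                     ceiling(seq_len(nrow(pairs)) / batchSize))
    epLoss <- 0
    for (b in batches) {
      fw <- modelForward(flat, relations, L, adjacency)
      bk <- modelBackward(flat, fw, relations, L, adjacency, NULL,
                          pairs[b, , drop = FALSE], y[b])
      stopIfNot(is.finite(bk$loss), "training diverged (non-finite loss)")
      st <- adamStep(flat, bk$grads, state, lr)
      flat <- st$params; state <- st$state
      epLoss <- epLoss + bk$loss * length(b)
    }
    losses[ep] <- epLoss / nrow(pairs)
    if (verbose) message(sprintf("pretrain epoch %d loss %.4f", ep, losses[ep]))
  }
  un <- unflattenParams(flat, relations, L)
  new("RepurposeModel", nodeIds = kg@nodes$id, X = un$X, W = un$W,
      decoder = un$decoder, relations = relations, layers = as.integer(L),
      dim = as.integer(d), pooling = list(active = FALSE),
      config = list(phase = "pretrain", epochs = epochs, lr = lr,
                    batchSize = batchSize, seed = seed),
      history = list(pretrainLoss = losses))
}

#' Fine-tune a pre-trained model on treatment relations
#'
#' Re-initialises the DistMult decoder vectors of the treatment relations
#' (indication, contraindication, off-label) and optimises only those
#' objectives on the training graph, with the degree-gated disease
#' augmentation active by default. Validation AUPRC (on the split's fixed
#' validation pairs plus seeded 1:1 negatives) is tracked each epoch and
#' the best-performing parameters are returned; training stops early after
#' \code{patience} epochs without improvement.
#'
#' @param model pre-trained \linkS4class{RepurposeModel}.
#' @param split a \linkS4class{KGSplit} (training happens on its train
#'   graph).
#' @param epochs maximum fine-tuning epochs.
#' @param lr Adam learning rate.
#' @param pooling activate disease augmentation.
#' @param poolK,gateScale,gateRate,gateFloor pooling configuration.
#' @param patience early-stopping patience in epochs.
#' @param batchSize pairs per gradient step.
#' @param seed integer seed.
#' @param verbose print progress.
#' @return A fine-tuned \linkS4class{RepurposeModel}.
#' @export
fineTuneModel <- function(model, split, epochs = 80, lr = 5e-4,
                          pooling = TRUE, poolK = 5, gateScale = 0.7,
                          gateRate = 0.7, gateFloor = 0.2, patience = 10,
                          batchSize = 8192, seed = 1, verbose = FALSE) {
  kg <- split@trainKG
  stopIfNot(identical(model@nodeIds, kg@nodes$id),
            "model and split refer to different node sets")
  stopIfNot(nrow(split@valid) > 0, "split has no validation pairs")
  relations <- model@relations
  L <- model@layers; d <- model@dim
  treat <- intersect(split@spec$treatmentRelations, relations)
  adjacency <- relationAdjacency(kg, relations)
  P <- NULL
  poolInfo <- list(active = FALSE)
  if (pooling) {
    P <- poolingOperator(kg, k = poolK, scale = gateScale, rate = gateRate,
                         floor = gateFloor)
    poolInfo <- list(active = TRUE, P = P, k = poolK,
                     gate = attr(P, "gate"),
                     degenerate = attr(P, "degenerate"))
  }
  # reinitialise treatment decoder vectors (avoid negative transfer)
  decoder <- model@decoder
  reinit <- withSeed(childSeed(seed, 3), {
    lapply(treat, function(r) as.numeric(xavierUniform(1, d, d = d)))
  })
  names(reinit) <- treat
  decoder[treat] <- reinit
  flat <- flattenParams(model@X, model@W, decoder)
  state <- adamInit(flat)

  treatRows <- which(kg@edges$relation %in% treat)
  stopIfNot(length(treatRows) > 0, "train graph has no treatment edges")
  ed <- kg@edges[treatRows, , drop = FALSE]
  pos <- data.frame(i = ed$head, j = ed$tail, relation = ed$relation,
                    stringsAsFactors = FALSE)
  edgeKeys <- kgEdgeKeys(kg)

  # fixed validation pairs: split positives + seeded negatives
  vNeg <- sampleNegatives(split@valid, kg, perPositive = 1L,
                          seed = childSeed(seed, 4))
  vAll <- rbind(split@valid, vNeg)
  vIdx <- data.frame(i = match(vAll$disease, kg@nodes$id),
                     j = match(vAll$drug, kg@nodes$id),
                     relation = vAll$relation, stringsAsFactors = FALSE)

  best <- list(flat = flat, auprc = -Inf, epoch = 0L)
  losses <- numeric(0); vals <- numeric(0)
  sinceBest <- 0L
  for (ep in seq_len(epochs)) {
    withSeed(childSeed(seed, 200 + ep), {
      neg <- corruptPairs(kg, pos, edgeKeys)
      pairs <- rbind(pos, neg)
      y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
      ord <- sample.int(nrow(pairs))
    })
    pairs <- pairs[ord, , drop = FALSE]; y <- y[ord]
    batches <- split(seq_len(nrow(pairs)),
                     ceiling(seq_len(nrow(pairs)) / batchSize))
    epLoss <- 0
    for (b in batches) {
      fw <- modelForward(flat, relations, L, adjacency, P)
      bk <- modelBackward(flat, fw, relations, L, adjacency, P,
                          pairs[b, , drop = FALSE], y[b])
      stopIfNot(is.finite(bk$loss), "training diverged (non-finite loss)")
      st <- adamStep(flat, bk$grads, state, lr)
      flat <- st$params; state <- st$state
      epLoss <- epLoss + bk$loss * length(b)
    }
    losses <- c(losses, epLoss / nrow(pairs))
    fw <- modelForward(flat, relations, L, adjacency, P)
    vp <- sigmoid(forwardScores(fw, vIdx, unflattenParams(flat, relations,
                                                          L)$decoder))
    va <- auprc(vp, vAll$label)
    vals <- c(vals, va)
    if (va > best$auprc) {
      best <- list(flat = flat, auprc = va, epoch = ep)
      sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    if (verbose) message(sprintf("finetune epoch %d loss %.4f valAUPRC %.3f",
                                 ep, losses[ep], va))
    if (sinceBest >= patience) break
  }
  un <- unflattenParams(best$flat, relations, L)
  new("RepurposeModel", nodeIds = model@nodeIds, X = un$X, W = un$W,
      decoder = un$decoder, relations = relations, layers = L, dim = d,
      pooling = poolInfo,
      config = c(model@config[setdiff(names(model@config), "phase")],
                 list(phase = "finetune", ftEpochs = epochs, ftLr = lr,
                      pooling = pooling, poolK = poolK, seed = seed,
                      bestEpoch = best$epoch)),
      history = c(model@history,
                  list(finetuneLoss = losses, validAUPRC = vals,
                       bestValidAUPRC = best$auprc)))
}

#' Score labelled pairs with a trained model
#'
#' Encodes the supplied graph with the model's parameters (applying the
#' model's disease pooling unless overridden) and returns the DistMult
#' likelihood of every pair.
#'
#' @param model a \linkS4class{RepurposeModel}.
#' @param kg graph to encode (node set must match the model's).
#' @param pairs data.frame with \code{disease}, \code{drug},
#'   \code{relation}.
#' @param pooling \code{"model"} (stored operator), \code{"recompute"}
#'   (rebuild from \code{kg}), or \code{"off"}.
#' @return numeric vector of likelihoods.
#' @export
scorePairs <- function(model, kg, pairs,
                       pooling = c("model", "recompute", "off")) {
  pooling <- match.arg(pooling)
  stopIfNot(identical(model@nodeIds, kg@nodes$id),
            "model and graph refer to different node sets")
  P <- NULL
  if (pooling == "model" && isTRUE(model@pooling$active)) P <- model@pooling$P
  if (pooling == "recompute" && isTRUE(model@pooling$active))
    P <- poolingOperator(kg, k = model@pooling$k)
  adjacency <- relationAdjacency(kg, model@relations)
  flat <- flattenParams(model@X, model@W, model@decoder)
  fw <- modelForward(flat, model@relations, model@layers, adjacency, P)
  idx <- data.frame(i = match(pairs$disease, kg@nodes$id),
                    j = match(pairs$drug, kg@nodes$id),
                    relation = pairs$relation, stringsAsFactors = FALSE)
  stopIfNot(!anyNA(idx$i) && !anyNA(idx$j), "pair endpoint not in graph")
  as.numeric(sigmoid(forwardScores(fw, idx, model@decoder)))
}

#' Rank candidate drugs for a disease
#'
#' Scores every drug node against the query disease under one treatment
#' relation and returns them in descending likelihood order (ties broken
#' by ascending drug id). Drugs already linked to the disease by any
#' treatment relation are omitted by default, matching the novel-candidate
#' protocol; set \code{includeKnown = TRUE} for benchmark splits.
#'
#' @param model trained \linkS4class{RepurposeModel}.
#' @param kg graph to encode.
#' @param disease query disease id.
#' @param relation treatment relation to predict (default indication).
#' @param includeKnown keep drugs already linked to the disease.
#' @return data.frame (\code{drug}, \code{likelihood}, \code{rank}).
#' @export
predictRankedDrugs <- function(model, kg, disease, relation = "indication",
                               includeKnown = FALSE) {
  stopIfNot(disease %in% kg@nodes$id, paste0("unknown disease id: ", disease))
  drugs <- nodeIdsOfType(kg, "drug")
  if (!includeKnown) {
    linked <- unique(unlist(lapply(TREATMENT_RELATIONS, function(r)
      neighborIds(kg, disease, r))))
    drugs <- setdiff(drugs, linked)
  }
  if (!length(drugs))
    return(data.frame(drug = character(), likelihood = numeric(),
                      rank = integer()))
  pairs <- data.frame(disease = disease, drug = drugs, relation = relation,
                      stringsAsFactors = FALSE)
  p <- scorePairs(model, kg, pairs)
  ord <- order(-p, drugs)
  data.frame(drug = drugs[ord], likelihood = p[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' Writes a binary checkpoint plus a JSON metadata sidecar (configuration,
#' dimensions, node-id hash). Loading reproduces predictions bit for bit.
#'
#' @param model a \linkS4class{RepurposeModel}.
#' @param path checkpoint file path.
#' @return \code{saveModel}: \code{path}, invisibly. \code{loadModel}: the
#'   restored model.
#' @export
saveModel <- function(model, path) {
  payload <- list(nodeIds = model@nodeIds, X = model@X, W = model@W,
                  decoder = model@decoder, relations = model@relations,
                  layers = model@layers, dim = model@dim,
                  pooling = model@pooling, config = model@config,
                  history = model@history)
  saveRDS(payload, path)
  meta <- list(dim = model@dim, layers = model@layers,
               relations = model@relations, config = model@config,
               nodeHash = sum(utf8ToInt(paste(model@nodeIds, collapse = ""))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- readRDS(path)
  new("RepurposeModel", nodeIds = p$nodeIds, X = p$X, W = p$W,
      decoder = p$decoder, relations = p$relations, layers = p$layers,
      dim = p$dim, pooling = p$pooling, config = p$config,
      history = p$history)
}

#' Export / import node embeddings as TSV
#'
#' Writes the model's encoded (optionally pooled) node embeddings as a
#' tabular TSV with a \code{node_id} column followed by d float columns.
#'
#' @param model trained \linkS4class{RepurposeModel}.
#' @param kg graph to encode.
#' @param path TSV path.
#' @param pooled apply the model's disease pooling before export.
#' @return \code{writeEmbeddings}: \code{path}, invisibly.
#'   \code{readEmbeddings}: numeric matrix with node-id rownames.
#' @export
writeEmbeddings <- function(model, kg, path, pooled = TRUE) {
  adjacency <- relationAdjacency(kg, model@relations)
  flat <- flattenParams(model@X, model@W, model@decoder)
  P <- if (pooled && isTRUE(model@pooling$active)) model@pooling$P else NULL
  H <- modelForward(flat, model@relations, model@layers, adjacency, P)$Hhat
  df <- data.frame(node_id = kg@nodes$id, H, stringsAsFactors = FALSE)
  names(df)[-1] <- paste0("e", seq_len(ncol(H)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$node_id
  M
}

#' Drug-popularity baseline scorer
#'
#' Sanity baseline: scores a (disease, drug) pair by the drug's treatment
#' degree in the graph (jittered deterministically by id for tie-breaks),
#' ignoring the disease entirely.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param pairs data.frame with a \code{drug} column.
#' @return numeric scores.
#' @export
degreeBaselineScores <- function(kg, pairs) {
  deg <- relationDegrees(kg, TREATMENT_RELATIONS)
  j <- match(pairs$drug, kg@nodes$id)
  deg[j] + (j %% 97) / 1e4
}

setMethod("show", "RepurposeModel", function(object) {
  cat("RepurposeModel: d =", object@dim, ", L =", object@layers,
      ",", length(object@relations), "relations,",
      length(object@nodeIds), "nodes\n")
  cat("  phase:", object@config$phase %||% "untrained",
      "| pooling:", if (isTRUE(object@pooling$active)) "on" else "off", "\n")
  if (!is.null(object@history$bestValidAUPRC))
    cat("  best validation AUPRC:",
        round(object@history$bestValidAUPRC, 4), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
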