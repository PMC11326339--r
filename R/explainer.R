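#' @include predictor.R
NULL

#' Gate opening probability for one message
#'
#' \eqn{\sigma(W_g [m_i || m_j] + bias)}: a single-layer network scores the
#' concatenated source and target messages; the location bias (3 at
#' initialisation) keeps gates open at the start of training so masking is
#' learned rather than imposed.
#'
#' @param mi,mj source and target message vectors.
#' @param wg gate weight vector of length \code{2 * length(mi)}.
#' @param bias location bias added inside the sigmoid.
#' @return probability strictly in (0, 1).
#' @export
gateProbability <- function(mi, mj, wg, bias = 3) {
  stopIfNot(length(wg) == length(mi) + length(mj),
            "gate weight length must match concatenated messages")
  as.numeric(sigmoid(sum(wg * c(mi, mj)) + bias))
}

#' Baseline substitution of a masked message
#'
#' \eqn{\hat m = z m + (1 - z) b}: a dropped message (z = 0) is replaced by
#' the learnable relation/layer baseline rather than removed, keeping the
#' mean aggregation well behaved. Relaxed \code{z} in [0, 1] interpolates.
#'
#' @param m message vector.
#' @param z gate decision in \{0,1\} (or [0,1] relaxed).
#' @param b baseline vector.
#' @return masked message.
#' @export
applyMask <- function(m, z, b) {
  stopIfNot(all(z >= 0 & z <= 1), "z must lie in [0,1]")
  z * m + (1 - z) * b
}

# ---- internal masked forward/backward -------------------------------------

gateParamsInit <- function(relations, L, d) {
  Wg <- lapply(relations, function(r) lapply(seq_len(L), function(l)
    c(numeric(2 * d), 0)))  # weights + intercept, all zero => open gates
  names(Wg) <- relations
  b <- lapply(relations, function(r) lapply(seq_len(L), function(l)
    numeric(d)))
  names(b) <- relations
  list(Wg = Wg, b = b)
}

# per-relation directed edge structures reused across epochs
edgeStructures <- function(kg, relations) {
  n <- nodeCount(kg)
  out <- lapply(relations, function(r) {
    de <- directedEdges(kg, r)
    if (!nrow(de)) return(NULL)
    deg <- tabulate(de$dst, nbins = n)
    Tm <- Matrix::sparseMatrix(i = de$dst, j = seq_len(nrow(de)),
                               x = 1 / deg[de$dst],
                               dims = c(n, nrow(de)))
    list(de = de, Tm = Tm)
  })
  names(out) <- relations
  out
}

# masked encode; returns layers plus per-layer per-relation gate records
maskedForward <- function(model, kg, gp, bias, es, P, hard = TRUE) {
  L <- model@layers
  relations <- names(es)
  layers <- vector("list", L + 1L)
  layers[[1]] <- model@X
  records <- vector("list", L)
  H <- model@X
  for (l in seq_len(L)) {
    Hl <- H
    rec <- list()
    for (r in relations) {
      st <- es[[r]]
      if (is.null(st)) next
      M <- H %*% t(model@W[[r]][[l]])
      gi <- cbind(M[st$de$src, , drop = FALSE], M[st$de$dst, , drop = FALSE])
      w <- gp$Wg[[r]][[l]]
      logit <- as.numeric(gi %*% w[-length(w)]) + w[length(w)] + bias
      pi <- as.numeric(sigmoid(logit))
      z <- if (hard) as.numeric(pi > 0.5) else pi
      b <- gp$b[[r]][[l]]
      msg <- z * M[st$de$src, , drop = FALSE] +
        outer(1 - z, b)
      Hl <- Hl + as.matrix(st$Tm %*% msg)
      rec[[r]] <- list(M = M, pi = pi, z = z, logit = logit)
    }
    records[[l]] <- rec
    H <- Hl
    layers[[l + 1L]] <- H
  }
  Hhat <- if (is.null(P)) H else as.matrix(P %*% H)
  list(layers = layers, H = H, Hhat = Hhat, records = records)
}

# gradient of loss = lambda * mean((phat-p0)^2) + sparsity mean(pi)
maskedBackward <- function(model, kg, gp, bias, es, P, fw, pairIdx, p0,
                           lambda) {
  L <- model@layers
  relations <- names(es)
  d <- model@dim
  n <- nrow(model@X)
  s <- numeric(nrow(pairIdx))
  for (r in unique(pairIdx$relation)) {
    sel <- pairIdx$relation == r
    A <- fw$Hhat[pairIdx$i[sel], , drop = FALSE]
    B <- fw$Hhat[pairIdx$j[sel], , drop = FALSE]
    s[sel] <- as.numeric((A * B) %*% model@decoder[[r]])
  }
  phat <- sigmoid(s)
  div <- mean((phat - p0)^2)
  dphat <- lambda * 2 * (phat - p0) / length(p0)
  g <- dphat * phat * (1 - phat)

  nGates <- sum(vapply(seq_len(L), function(l)
    sum(vapply(fw$records[[l]], function(x) length(x$pi), numeric(1))),
    numeric(1)))

  Ghat <- matrix(0, n, d)
  for (r in unique(pairIdx$relation)) {
    sel <- pairIdx$relation == r
    A <- fw$Hhat[pairIdx$i[sel], , drop = FALSE]
    B <- fw$Hhat[pairIdx$j[sel], , drop = FALSE]
    wr <- model@decoder[[r]]
    Ghat <- accumRows(Ghat, pairIdx$i[sel], g[sel] * sweep(B, 2, wr, "*"))
    Ghat <- accumRows(Ghat, pairIdx$j[sel], g[sel] * sweep(A, 2, wr, "*"))
  }
  G <- if (is.null(P)) Ghat else as.matrix(Matrix::t(P) %*% Ghat)

  grads <- list()
  for (l in rev(seq_len(L))) {
    Gprev <- G
    for (r in relations) {
      st <- es[[r]]
      if (is.null(st)) next
      rec <- fw$records[[l]][[r]]
      dmsg <- as.matrix(Matrix::t(st$Tm) %*% G)          # nEdge x d
      Msrc <- rec$M[st$de$src, , drop = FALSE]
      b <- gp$b[[r]][[l]]
      dz <- rowSums(dmsg * sweep(Msrc, 2, b, "-"))
      db <- colSums((1 - rec$z) * dmsg)
      dM <- matrix(0, n, d)
      dM <- accumRows(dM, st$de$src, rec$z * dmsg)
      # straight-through: indicator treated as identity wrt pi; plus the
      # sparsity term d(mean pi)/dpi = 1/nGates
      dpi <- dz + 1 / nGates
      dlogit <- dpi * rec$pi * (1 - rec$pi)
      w <- gp$Wg[[r]][[l]]
      wgGrad <- c(as.numeric(crossprod(
        cbind(Msrc, rec$M[st$de$dst, , drop = FALSE]), dlogit)),
        sum(dlogit))
      wMain <- w[-length(w)]
      dM <- accumRows(dM, st$de$src,
                      dlogit * matrix(wMain[seq_len(d)], nrow = length(dlogit),
                                      ncol = d, byrow = TRUE))
      dM <- accumRows(dM, st$de$dst,
                      dlogit * matrix(wMain[d + seq_len(d)],
                                      nrow = length(dlogit), ncol = d,
                                      byrow = TRUE))
      grads[[paste0("Wg.", r, ".", l)]] <- wgGrad
      grads[[paste0("b.", r, ".", l)]] <- db
      Gprev <- Gprev + dM %*% model@W[[r]][[l]]
    }
    G <- Gprev
  }
  sparsity <- mean(unlist(lapply(fw$records, function(rec)
    lapply(rec, function(x) x$z))))
  list(grads = grads, divergence = div, sparsity = sparsity, phat = phat)
}

#' Train the edge-masking explainer
#'
#' Optimises amortised per-(relation, layer) gate networks and baseline
#' vectors on a frozen predictor, under the Lagrangian objective:
#' minimise the number of open gates subject to the masked predictions
#' staying within a squared-divergence margin \code{beta} of the original
#' predictions. The multiplier ascends on the constraint violation and is
#' clipped at zero. Predictor weights are never modified.
#'
#' @param model trained (frozen) \linkS4class{RepurposeModel}.
#' @param kg graph the explanations live on (typically the training graph).
#' @param pairs query pairs (\code{disease}, \code{drug}, \code{relation})
#'   whose predictions must be preserved.
#' @param epochs gate-training epochs.
#' @param lr Adam learning rate for gate parameters.
#' @param lrLambda ascent rate for the multiplier.
#' @param beta faithfulness margin (mean squared divergence budget).
#' @param bias location bias inside the gate sigmoid at initialisation.
#' @param seed integer seed.
#' @param verbose print progress.
#' @return An \linkS4class{EdgeGates}.
#' @export
trainExplainer <- function(model, kg, pairs, epochs = 300, lr = 2e-2,
                           lrLambda = 1, beta = 0.03, bias = 3, seed = 1,
                           verbose = FALSE) {
  stopIfNot(identical(model@nodeIds, kg@nodes$id),
            "model and graph refer to different node sets")
  relations <- model@relations
  L <- model@layers
  es <- edgeStructures(kg, relations)
  P <- if (isTRUE(model@pooling$active)) model@pooling$P else NULL
  gp <- gateParamsInit(relations, L, model@dim)
  idx <- data.frame(i = match(pairs$disease, kg@nodes$id),
                    j = match(pairs$drug, kg@nodes$id),
                    relation = pairs$relation, stringsAsFactors = FALSE)
  stopIfNot(!anyNA(idx$i) && !anyNA(idx$j), "pair endpoint not in graph")
  # original (unmasked) predictions, fixed targets
  adjacency <- relationAdjacency(kg, relations)
  flat <- flattenParams(model@X, model@W, model@decoder)
  fw0 <- modelForward(flat, relations, L, adjacency, P)
  p0 <- as.numeric(sigmoid(forwardScores(fw0, idx, model@decoder)))

  gateFlat <- list()
  for (r in relations) for (l in seq_len(L)) {
    gateFlat[[paste0("Wg.", r, ".", l)]] <- gp$Wg[[r]][[l]]
    gateFlat[[paste0("b.", r, ".", l)]] <- gp$b[[r]][[l]]
  }
  state <- adamInit(gateFlat)
  lambda <- 1
  divs <- numeric(epochs); spars <- numeric(epochs); lambdas <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (r in relations) for (l in seq_len(L)) {
      gp$Wg[[r]][[l]] <- gateFlat[[paste0("Wg.", r, ".", l)]]
      gp$b[[r]][[l]] <- gateFlat[[paste0("b.", r, ".", l)]]
    }
    fw <- maskedForward(model, kg, gp, bias, es, P, hard = TRUE)
    bk <- maskedBackward(model, kg, gp, bias, es, P, fw, idx, p0, lambda)
    stopIfNot(all(vapply(bk$grads, function(x) all(is.finite(x)),
                         logical(1))), "explainer training diverged")
    grads <- gateFlat
    for (k in names(grads)) grads[[k]] <-
      if (!is.null(bk$grads[[k]])) bk$grads[[k]] else grads[[k]] * 0
    st <- adamStep(gateFlat, grads, state, lr)
    gateFlat <- st$params; state <- st$state
    lambda <- max(0, lambda + lrLambda * (bk$divergence - beta))
    divs[ep] <- bk$divergence; spars[ep] <- bk$sparsity
    lambdas[ep] <- lambda
    if (verbose)
      message(sprintf("explainer epoch %d div %.5f open %.3f lambda %.3f",
                      ep, bk$divergence, bk$sparsity, lambda))
  }
  for (r in relations) for (l in seq_len(L)) {
    gp$Wg[[r]][[l]] <- gateFlat[[paste0("Wg.", r, ".", l)]]
    gp$b[[r]][[l]] <- gateFlat[[paste0("b.", r, ".", l)]]
  }
  new("EdgeGates", Wg = gp$Wg, baseline = gp$b, bias = bias,
      lambda = lambda, relations = relations, layers = L,
      history = list(divergence = divs, openFraction = spars,
                     lambda = lambdas))
}

#' Predictions under the trained mask
#'
#' Runs the masked forward pass (hard gates, baseline substitution) and
#' returns the likelihood of each query pair, for comparison with the
#' unmasked predictions.
#'
#' @param gates an \linkS4class{EdgeGates}.
#' @param model the frozen \linkS4class{RepurposeModel}.
#' @param kg the graph.
#' @param pairs data.frame (\code{disease}, \code{drug}, \code{relation}).
#' @return numeric vector of masked likelihoods.
#' @export
maskedPredictions <- function(gates, model, kg, pairs) {
  es <- edgeStructures(kg, gates@relations)
  P <- if (isTRUE(model@pooling$active)) model@pooling$P else NULL
  gp <- list(Wg = gates@Wg, b = gates@baseline)
  fw <- maskedForward(model, kg, gp, gates@bias, es, P, hard = TRUE)
  idx <- data.frame(i = match(pairs$disease, kg@nodes$id),
                    j = match(pairs$drug, kg@nodes$id),
                    relation = pairs$relation, stringsAsFactors = FALSE)
  s <- numeric(nrow(idx))
  for (r in unique(idx$relation)) {
    sel <- idx$relation == r
    A <- fw$Hhat[idx$i[sel], , drop = FALSE]
    B <- fw$Hhat[idx$j[sel], , drop = FALSE]
    s[sel] <- as.numeric((A * B) %*% model@decoder[[r]])
  }
  as.numeric(sigmoid(s))
}

#' Per-edge importance scores
#'
#' The pre-indicator gate value quantifies each edge's contribution. Gate
#' probabilities are read off the masked forward pass (the dynamics the
#' gates were trained under) and aggregated to one score per undirected
#' edge by the maximum over layers and message directions; an edge is
#' retained when its importance exceeds 0.5.
#'
#' @param gates trained \linkS4class{EdgeGates}.
#' @param model the frozen \linkS4class{RepurposeModel} they explain.
#' @param kg the graph.
#' @return data.frame (\code{head_id}, \code{relation}, \code{tail_id},
#'   \code{importance}, \code{retained}), one row per undirected edge.
#' @export
edgeImportances <- function(gates, model, kg) {
  relations <- gates@relations
  L <- gates@layers
  es <- edgeStructures(kg, relations)
  P <- if (isTRUE(model@pooling$active)) model@pooling$P else NULL
  gp <- list(Wg = gates@Wg, b = gates@baseline)
  fw <- maskedForward(model, kg, gp, gates@bias, es, P, hard = TRUE)
  imp <- rep(0, edgeCount(kg))
  for (l in seq_len(L)) {
    for (r in relations) {
      st <- es[[r]]
      if (is.null(st)) next
      pi <- fw$records[[l]][[r]]$pi
      best <- tapply(pi, st$de$edge, max)
      at <- as.integer(names(best))
      imp[at] <- pmax(imp[at], as.numeric(best))
    }
  }
  ed <- kgEdges(kg)
  data.frame(ed, importance = imp, retained = imp > 0.5,
             stringsAsFactors = FALSE)
}

#' Extract multi-hop explanation paths
#'
#' Enumerates all simple paths of at most \code{maxHops} edges between the
#' query drug and disease through retained edges, scored by the minimum
#' edge importance along the path (bottleneck score) and ranked by score.
#' Parallel edges between a node pair are collapsed to the most important
#' one for path-finding.
#'
#' @param kg the graph.
#' @param importances output of [edgeImportances()].
#' @param drug,disease query node ids.
#' @param maxHops maximum path length in edges (>= 1).
#' @return list of paths, each a list with \code{nodes}, \code{relations}
#'   and \code{score}; empty list when no retained path connects the pair.
#' @export
extractPaths <- function(kg, importances, drug, disease, maxHops = 3) {
  stopIfNot(maxHops >= 1, "maxHops must be >= 1")
  stopIfNot(all(c(drug, disease) %in% kg@nodes$id),
            "query endpoints absent from graph")
  kept <- importances[importances$retained, , drop = FALSE]
  if (!nrow(kept)) return(list())
  # collapse parallel edges: keep the most important relation per pair
  key <- paste(pmin(kept$head_id, kept$tail_id),
               pmax(kept$head_id, kept$tail_id))
  kept <- kept[order(key, -kept$importance), , drop = FALSE]
  kept <- kept[!duplicated(sort(key)), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$head_id, to = kept$tail_id,
               relation = kept$relation, importance = kept$importance),
    directed = FALSE,
    vertices = kg@nodes$id)
  if (!drug %in% names(igraph::V(g)) || !disease %in% names(igraph::V(g)))
    return(list())
  paths <- igraph::all_simple_paths(g, from = drug, to = disease,
                                    cutoff = maxHops)
  out <- lapply(paths, function(vp) {
    ids <- names(vp)
    eids <- igraph::get_edge_ids(g, rep(ids, each = 2)[-c(1, 2 * length(ids))])
    list(nodes = ids,
         relations = igraph::edge_attr(g, "relation", eids),
         score = min(igraph::edge_attr(g, "importance", eids)))
  })
  out[order(-vapply(out, `[[`, numeric(1), "score"))]
}

#' Score pairs with a fixed edge mask
#'
#' Runs the forward pass with a prescribed keep/drop decision per
#' undirected edge: kept edges pass their true messages, dropped edges are
#' substituted with the explainer's learned baseline for their relation
#' and layer. This is the explainer's own counterfactual for edge removal
#' and preserves the mean-aggregation geometry (neighbour counts are
#' unchanged), unlike deleting edges from the graph.
#'
#' @param model frozen \linkS4class{RepurposeModel}.
#' @param gates trained \linkS4class{EdgeGates} (provides the baselines).
#' @param kg the graph.
#' @param pairs data.frame (\code{disease}, \code{drug}, \code{relation}).
#' @param keep logical vector over \code{kgEdges(kg)} rows.
#' @return numeric vector of likelihoods.
#' @export
maskedScorePairs <- function(model, gates, kg, pairs, keep) {
  stopIfNot(length(keep) == edgeCount(kg),
            "keep must flag every edge of kg")
  relations <- gates@relations
  L <- gates@layers
  es <- edgeStructures(kg, relations)
  P <- if (isTRUE(model@pooling$active)) model@pooling$P else NULL
  H <- model@X
  for (l in seq_len(L)) {
    Hl <- H
    for (r in relations) {
      st <- es[[r]]
      if (is.null(st)) next
      M <- H %*% t(model@W[[r]][[l]])
      z <- as.numeric(keep[st$de$edge])
      b <- gates@baseline[[r]][[l]]
      msg <- z * M[st$de$src, , drop = FALSE] + outer(1 - z, b)
      Hl <- Hl + as.matrix(st$Tm %*% msg)
    }
    H <- Hl
  }
  Hhat <- if (is.null(P)) H else as.matrix(P %*% H)
  idx <- data.frame(i = match(pairs$disease, kg@nodes$id),
                    j = match(pairs$drug, kg@nodes$id),
                    relation = pairs$relation, stringsAsFactors = FALSE)
  s <- numeric(nrow(idx))
  for (r in unique(idx$relation)) {
    sel <- idx$relation == r
    A <- Hhat[idx$i[sel], , drop = FALSE]
    B <- Hhat[idx$j[sel], , drop = FALSE]
    s[sel] <- as.numeric((A * B) %*% model@decoder[[r]])
  }
  as.numeric(sigmoid(s))
}

#' Explanation fidelity metrics
#'
#' \describe{
#'   \item{insertion}{AUPRC using only the top K percent of edges ranked
#'     by importance (100 percent equals the full graph).}
#'   \item{deletion}{AUPRC after removing the top K percent (0 percent
#'     equals the full graph).}
#'   \item{stability}{Pearson correlation of edge importances before and
#'     after removing a random fraction of edges from the graph.}
#' }
#' Insertion and deletion use the explainer's masking semantics
#' ([maskedScorePairs()]): an excluded edge's messages are replaced by the
#' learned baselines. Stability perturbs the graph itself.
#'
#' @param model frozen \linkS4class{RepurposeModel}.
#' @param gates trained \linkS4class{EdgeGates}.
#' @param kg the graph the importances refer to.
#' @param pairs labelled pairs (\code{disease}, \code{drug},
#'   \code{relation}, \code{label}) to evaluate on.
#' @param kGrid fractions (0-1] for insertion/deletion.
#' @param perturbGrid edge-removal fractions for stability.
#' @param seed seed for the stability perturbations.
#' @return list with \code{insertion}, \code{deletion} (named AUPRC
#'   vectors), \code{stability} (named correlation vector) and the
#'   importance table used.
#' @export
fidelityMetrics <- function(model, gates, kg, pairs,
                            kGrid = c(0.1, 0.2, 0.5, 1),
                            perturbGrid = c(0.01, 0.05, 0.1), seed = 1) {
  stopIfNot(any(pairs$label == 1) && any(pairs$label == 0),
            "pairs must contain both classes")
  imp <- edgeImportances(gates, model, kg)
  ord <- order(-imp$importance)
  m <- edgeCount(kg)
  evalOn <- function(keepRows) {
    keep <- logical(m); keep[keepRows] <- TRUE
    auprc(maskedScorePairs(model, gates, kg, pairs, keep), pairs$label)
  }
  insertion <- vapply(kGrid, function(k) {
    top <- ord[seq_len(max(1L, round(k * m)))]
    if (k >= 1) top <- seq_len(m)
    evalOn(top)
  }, numeric(1))
  deletion <- vapply(kGrid, function(k) {
    top <- if (k <= 0) integer(0) else ord[seq_len(round(k * m))]
    evalOn(setdiff(seq_len(m), top))
  }, numeric(1))
  names(insertion) <- names(deletion) <- paste0("K", kGrid * 100)
  stability <- vapply(seq_along(perturbGrid), function(ix) {
    f <- perturbGrid[ix]
    drop <- withSeed(childSeed(seed, ix),
                     sample.int(m, max(1L, round(f * m))))
    sub <- dropEdges(kg, drop)
    imp2 <- edgeImportances(gates, model, sub)
    keyFull <- paste(imp$head_id, imp$relation, imp$tail_id)
    keySub <- paste(imp2$head_id, imp2$relation, imp2$tail_id)
    common <- match(keySub, keyFull)
    suppressWarnings(cor(imp$importance[common], imp2$importance))
  }, numeric(1))
  names(stability) <- paste0("drop", perturbGrid * 100)
  list(insertion = insertion, deletion = deletion, stability = stability,
       importances = imp)
}

#' Retained-versus-complement sufficiency contrast
#'
#' Compares AUPRC when predictions use only the retained (importance >
#' 0.5) edges versus only the complement, under the explainer's masking
#' semantics: a faithful explainer's retained subgraph degrades
#' performance far less than its complement.
#'
#' @inheritParams fidelityMetrics
#' @return named numeric vector (\code{full}, \code{retained},
#'   \code{complement}).
#' @export
retainedComplementAUPRC <- function(model, gates, kg, pairs) {
  imp <- edgeImportances(gates, model, kg)
  full <- auprc(scorePairs(model, kg, pairs, pooling = "model"),
                pairs$label)
  retained <- auprc(maskedScorePairs(model, gates, kg, pairs, imp$retained),
                    pairs$label)
  complement <- auprc(maskedScorePairs(model, gates, kg, pairs,
                                       !imp$retained), pairs$label)
  c(full = full, retained = retained, complement = complement)
}

setMethod("show", "EdgeGates", function(object) {
  cat("EdgeGates:", length(object@relations), "relations x",
      object@layers, "layers; lambda =", round(object@lambda, 3), "\n")
  h <- object@history
  if (length(h$openFraction))
    cat("  final open-gate fraction:",
        round(h$openFraction[length(h$openFraction)], 3),
        "| divergence:", signif(h$divergence[length(h$divergence)], 3), "\n")
})
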