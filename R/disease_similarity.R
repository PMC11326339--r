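#' @include knowledge_graph.R
NULL

SIGNATURE_TYPES <- c("gene/protein", "effect/phenotype", "exposure", "disease")

#' Disease signature vectors
#'
#' The signature of a disease is a binary indicator vector over four
#' concatenated blocks -- the gene/protein, effect/phenotype, exposure and
#' disease nodes of the graph -- with a 1 wherever that node lies in the
#' disease's 1-hop neighbourhood. The dot product of two signatures counts
#' their shared neighbours across the four types.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param diseases disease ids (default: all disease nodes).
#' @return \code{diseaseSignatures}: sparse binary matrix
#'   (diseases x signature dimension), block offsets in attribute
#'   \code{"blocks"}. \code{diseaseSignature}: one dense named vector.
#' @export
diseaseSignatures <- function(kg, diseases = nodeIdsOfType(kg, "disease")) {
  nd <- kg@nodes
  dIdx <- match(diseases, nd$id)
  stopIfNot(!anyNA(dIdx), "unknown disease id")
  stopIfNot(all(nd$type[dIdx] == "disease"),
            "signatures are defined for disease nodes only")
  colIdx <- unlist(lapply(SIGNATURE_TYPES, function(t) which(nd$type == t)))
  colPos <- integer(nrow(nd)); colPos[colIdx] <- seq_along(colIdx)
  blocks <- cumsum(vapply(SIGNATURE_TYPES,
                          function(t) sum(nd$type == t), integer(1)))
  ed <- kg@edges
  rowPos <- integer(nrow(nd)); rowPos[dIdx] <- seq_along(dIdx)
  pairs <- rbind(cbind(ed$head, ed$tail), cbind(ed$tail, ed$head))
  sel <- rowPos[pairs[, 1]] > 0L & colPos[pairs[, 2]] > 0L
  # exclude the disease itself (a self-neighbour never arises: no loops)
  i <- rowPos[pairs[sel, 1]]; j <- colPos[pairs[sel, 2]]
  S <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(dIdx), length(colIdx)),
                            dimnames = list(diseases, nd$id[colIdx]))
  S@x[] <- 1  # collapse multi-relation neighbours to a binary indicator
  S <- Matrix::drop0(S)
  attr(S, "blocks") <- blocks
  S
}

#' @rdname diseaseSignatures
#' @param disease a single disease id.
#' @export
diseaseSignature <- function(kg, disease) {
  S <- diseaseSignatures(kg, disease)
  stats::setNames(as.numeric(S[1, ]), colnames(S))
}

#' Signature similarity
#'
#' Unnormalised mode (the default, used for ranking and pooling weights)
#' is the plain dot product: the count of shared 1-hop neighbours across
#' the four signature node types. Normalised mode is the cosine of the two
#' signatures, used for reporting and diagnostics.
#'
#' @param p,q signature vectors of equal dimension.
#' @param normalized cosine-normalise the dot product.
#' @return numeric score (a non-negative integer count when unnormalised).
#' @export
signatureSimilarity <- function(p, q, normalized = FALSE) {
  stopIfNot(length(p) == length(q), "signature dimension mismatch")
  s <- sum(p * q)
  if (normalized) {
    np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
    s <- if (np > 0 && nq > 0) s / (np * nq) else 0
  }
  s
}

#' Most similar diseases for a query
#'
#' Ranks all other diseases by unnormalised signature similarity to the
#' query; ties (and the all-zero degenerate case) break deterministically
#' by ascending node id.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param disease query disease id.
#' @param k number of similar diseases to retrieve (>= 1).
#' @param signatures optional precomputed [diseaseSignatures()] matrix.
#' @return data.frame (\code{disease}, \code{score}, \code{cosine}) in rank
#'   order; fewer than k rows (with a warning) when the graph has fewer
#'   other diseases.
#' @export
topKSimilar <- function(kg, disease, k = 5, signatures = NULL) {
  stopIfNot(k >= 1, "k must be >= 1")
  if (is.null(signatures)) signatures <- diseaseSignatures(kg)
  all <- rownames(signatures)
  stopIfNot(disease %in% all, paste0("unknown disease id: ", disease))
  others <- setdiff(all, disease)
  if (length(others) < k) {
    warning("fewer than k other diseases; returning all")
    k <- length(others)
  }
  p <- signatures[disease, , drop = FALSE]
  scores <- as.numeric(signatures[others, , drop = FALSE] %*% Matrix::t(p))
  norms <- sqrt(Matrix::rowSums(signatures[others, , drop = FALSE]^2))
  np <- sqrt(sum(p^2))
  cosine <- ifelse(norms > 0 & np > 0, scores / (norms * np), 0)
  ord <- order(-scores, others)
  if (all(scores == 0))
    warning("query signature has no overlap with any disease; ",
            "ranking is the id tie-break")
  sel <- ord[seq_len(k)]
  data.frame(disease = others[sel], score = scores[sel],
             cosine = cosine[sel], stringsAsFactors = FALSE)
}

#' Similarity-weighted aggregation of disease embeddings
#'
#' \eqn{h^{sim} = \sum_j (sim_j / \sum_k sim_k) h_j}: a convex combination
#' of the retrieved diseases' embeddings weighted by similarity score.
#' When every score is zero no information can be borrowed; the zero
#' vector is returned with attribute \code{"degenerate" = TRUE} so the
#' caller (the gate) can fall back to the original embedding.
#'
#' @param H numeric matrix (retrieved diseases x d) of embeddings.
#' @param scores similarity scores aligned with rows of \code{H}.
#' @return length-d numeric vector.
#' @export
aggregateSimilar <- function(H, scores) {
  stopIfNot(nrow(H) == length(scores), "scores do not align with embeddings")
  tot <- sum(scores)
  if (tot <= 0) {
    out <- numeric(ncol(H))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(crossprod(H, scores / tot))
}

#' Degree-adjusted gating coefficient
#'
#' \eqn{c = scale \cdot e^{-\lambda \, degree} + floor} (defaults
#' \eqn{0.7 e^{-0.7 d} + 0.2}): close to 0.9 for diseases with no
#' treatment edges, decaying rapidly to the floor 0.2 for well-annotated
#' diseases, so that borrowing from similar diseases is strong exactly
#' where the graph is thin.
#'
#' @param degree node degree (>= 0) over the gating relations.
#' @param scale,rate,floor gate constants (all configurable).
#' @return gate value in \code{(floor, floor + scale]}.
#' @export
gateCoefficient <- function(degree, scale = 0.7, rate = 0.7, floor = 0.2) {
  stopIfNot(all(degree >= 0), "degree must be non-negative")
  stopIfNot(scale > 0 && rate > 0 && floor >= 0, "invalid gate constants")
  scale * exp(-rate * degree) + floor
}

#' Gated embedding augmentation
#'
#' \eqn{\hat h = c \, h^{sim} + (1 - c) h}: convex combination of the
#' disease's own embedding and the borrowed similarity-pooled embedding.
#'
#' @param h original embedding.
#' @param hsim pooled embedding from [aggregateSimilar()].
#' @param c gate coefficient in [0, 1].
#' @return augmented embedding vector.
#' @export
augmentEmbedding <- function(h, hsim, c) {
  stopIfNot(c >= 0 && c <= 1, "gate coefficient must be in [0,1]")
  c * hsim + (1 - c) * h
}

#' Disease-pooling operator
#'
#' Builds the fixed linear operator P (sparse, nodes x nodes) that applies
#' degree-gated similarity pooling to every disease row of an embedding
#' matrix: for disease i with retrieved similar diseases j and gate c_i,
#' row i is \eqn{(1-c_i) e_i + c_i \sum_j w_{ij} e_j}; all other rows are
#' identity. Signatures, similarities and gate degrees are computed on the
#' supplied (training) graph only. Diseases whose retrieved scores are all
#' zero keep an identity row and are flagged.
#'
#' @param kg training \linkS4class{KnowledgeGraph}.
#' @param k similar diseases retrieved per query.
#' @param scale,rate,floor gate constants, see [gateCoefficient()].
#' @param degreeRelations relations whose degree feeds the gate (default:
#'   the treatment relations).
#' @return sparse matrix P with attributes \code{"gate"} (per-disease gate
#'   values) and \code{"degenerate"} (ids with no similar disease found).
#' @export
poolingOperator <- function(kg, k = 5, scale = 0.7, rate = 0.7, floor = 0.2,
                            degreeRelations = TREATMENT_RELATIONS) {
  n <- nodeCount(kg)
  S <- diseaseSignatures(kg)
  diseases <- rownames(S)
  dIdx <- match(diseases, kg@nodes$id)
  deg <- relationDegrees(kg, degreeRelations)[dIdx]
  gate <- gateCoefficient(deg, scale = scale, rate = rate, floor = floor)
  names(gate) <- diseases
  sim <- as.matrix(S %*% Matrix::t(S))
  diag(sim) <- -Inf  # self never retrieved
  kEff <- min(k, length(diseases) - 1L)
  triplets <- list(data.frame(i = seq_len(n), j = seq_len(n), x = 1))
  degenerate <- character(0)
  for (a in seq_along(diseases)) {
    ord <- order(-sim[a, ], diseases)
    sel <- ord[seq_len(kEff)]
    w <- sim[a, sel]
    if (sum(w) <= 0) { degenerate <- c(degenerate, diseases[a]); next }
    w <- w / sum(w)
    keep <- w > 0
    triplets[[length(triplets) + 1L]] <- data.frame(
      i = dIdx[a], j = dIdx[sel[keep]], x = gate[a] * w[keep])
    triplets[[1]]$x[dIdx[a]] <- 1 - gate[a]
  }
  tr <- do.call(rbind, triplets)
  P <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  attr(P, "gate") <- gate
  attr(P, "degenerate") <- degenerate
  P
}
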