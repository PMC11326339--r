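#' @include knowledge_graph.R
NULL

#' Initialise node embeddings
#'
#' Draws each initial embedding entry i.i.d. Xavier-uniform on
#' \eqn{[-a, a]} with \eqn{a = \sqrt{6/(fan_{in}+fan_{out})}} under the
#' convention \eqn{fan_{in} = fan_{out} = d}, i.e. \eqn{a = \sqrt{3/d}}.
#'
#' @param kg a \linkS4class{KnowledgeGraph} (rows follow its node order).
#' @param d embedding dimension (>= 1).
#' @param seed integer seed; the same seed reproduces the table.
#' @return numeric matrix (nodes x d) with rownames = node ids.
#' @export
initEmbeddings <- function(kg, d = 128, seed = 1) {
  stopIfNot(d >= 1, "d must be >= 1")
  X <- withSeed(seed, xavierUniform(nodeCount(kg), d, d = d))
  rownames(X) <- kg@nodes$id
  X
}

#' Relation-specific message propagation
#'
#' Computes the message each node emits under one relation at one layer:
#' \eqn{m_{r,i} = W_r h_i}, i.e. a relation-specific linear map of the
#' previous layer's embedding. Messages depend only on the source node and
#' are shared by all its targets.
#'
#' @param H numeric matrix (nodes x d), previous-layer embeddings.
#' @param W numeric d x d relation weight matrix.
#' @return numeric matrix of messages, same shape as \code{H}.
#' @export
relationMessages <- function(H, W) {
  stopIfNot(ncol(H) == ncol(W) && nrow(W) == ncol(W),
            "shape mismatch between embeddings and weight matrix")
  H %*% t(W)
}

#' Mean aggregation of incoming messages
#'
#' For each node j, averages the messages of its relation-r neighbours:
#' \eqn{\tilde m_j = |N_j^r|^{-1} \sum_{i \in N_j^r} m_{r,i}}. Nodes with
#' no neighbours under the relation receive the zero vector.
#'
#' @param M message matrix (nodes x d) from [relationMessages()].
#' @param A sparse mean-aggregation operator for the relation
#'   (\code{A[j,i] = 1/|N_j^r|} for each directed message i to j).
#' @return numeric matrix (nodes x d) of aggregated messages.
#' @export
aggregateMessages <- function(M, A) {
  as.matrix(A %*% M)
}

#' Residual embedding update
#'
#' \eqn{h^l = h^{l-1} + \sum_r \tilde m_r}: adds the aggregated messages of
#' every relation onto the previous layer's embedding. No nonlinearity is
#' applied between layers (the update is implemented literally); an
#' optional elementwise \code{tanh} can be switched on for experimentation.
#'
#' @param H previous-layer embeddings (nodes x d).
#' @param aggregates list of aggregated message matrices, one per relation.
#' @param nonlinear apply \code{tanh} after the residual sum (default off).
#' @return numeric matrix, the updated layer.
#' @export
updateEmbeddings <- function(H, aggregates, nonlinear = FALSE) {
  out <- H
  for (Ag in aggregates) out <- out + Ag
  if (nonlinear) out <- tanh(out)
  out
}

# fresh relation parameters (message weights + decoder vectors)
initRelationParams <- function(relations, d, L, seed = 1) {
  withSeed(seed, {
    W <- lapply(relations, function(r)
      lapply(seq_len(L), function(l) xavierUniform(d, d, d = d)))
    names(W) <- relations
    decoder <- lapply(relations, function(r) as.numeric(xavierUniform(1, d, d = d)))
    names(decoder) <- relations
    list(W = W, decoder = decoder)
  })
}

#' Encode a knowledge graph
#'
#' Runs L layers of relation-specific message passing
#' (propagate, mean-aggregate, residual update) over all relations and
#' returns the final node embeddings. On a graph with no edges the output
#' equals the initial embeddings.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param X initial embeddings (nodes x d), rows in \code{kg} node order.
#' @param W list over relations of lists over layers of d x d matrices.
#' @param L number of layers (>= 1).
#' @param adjacency optional precomputed [relationAdjacency()] list.
#' @param nonlinear passed to [updateEmbeddings()].
#' @param allLayers return the list \code{h^0 .. h^L} instead of \code{h^L}.
#' @return embeddings matrix (nodes x d), or list of per-layer matrices.
#' @export
encodeGraph <- function(kg, X, W, L = length(W[[1]]), adjacency = NULL,
                        nonlinear = FALSE, allLayers = FALSE) {
  stopIfNot(L >= 1, "L must be >= 1")
  relations <- names(W)
  if (is.null(adjacency)) adjacency <- relationAdjacency(kg, relations)
  layers <- vector("list", L + 1L)
  layers[[1]] <- X
  H <- X
  for (l in seq_len(L)) {
    aggs <- lapply(relations, function(r)
      aggregateMessages(relationMessages(H, W[[r]][[l]]), adjacency[[r]]))
    H <- updateEmbeddings(H, aggs, nonlinear = nonlinear)
    layers[[l + 1L]] <- H
  }
  if (allLayers) layers else H
}
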