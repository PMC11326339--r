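#' Heterogeneous knowledge graph
#'
#' Typed nodes joined by typed undirected edges. Nodes live in a table whose
#' row order defines the internal integer index used throughout the package;
#' edges store integer endpoints into that table plus a relation label.
#' Edges are canonicalised (endpoint ids sorted lexicographically within each
#' edge) so that \code{(i, r, j)} and \code{(j, r, i)} are the same edge.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}, \code{name};
#'   \code{id} values are unique.
#' @slot edges data.frame with integer columns \code{head}, \code{tail}
#'   (row indices into \code{nodes}) and character column \code{relation}.
#' @slot nodeTypes character vector, the declared node-type vocabulary.
#' @slot relationTypes character vector, the declared relation vocabulary.
#'
#' @export
setClass("KnowledgeGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    nodeTypes = "character",
    relationTypes = "character"
  )
)

setValidity("KnowledgeGraph", function(object) {
  msgs <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "type", "name") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns id, type, name")
  else {
    if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
    if (!all(nd$type %in% object@nodeTypes))
      msgs <- c(msgs, "node types outside declared vocabulary")
  }
  if (!all(c("head", "relation", "tail") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns head, relation, tail")
  else if (nrow(ed)) {
    if (!is.integer(ed$head) || !is.integer(ed$tail))
      msgs <- c(msgs, "edge endpoints must be integer node indices")
    else if (any(ed$head < 1L | ed$head > nrow(nd) |
                 ed$tail < 1L | ed$tail > nrow(nd)))
      msgs <- c(msgs, "edge endpoint index out of range")
    if (!all(ed$relation %in% object@relationTypes))
      msgs <- c(msgs, "edge relations outside declared vocabulary")
    key <- canonicalEdgeKey(nd$id[ed$head], ed$relation, nd$id[ed$tail])
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate undirected edges present")
  }
  if (length(msgs)) msgs else TRUE
})

#' Curated evaluation split of a knowledge graph
#'
#' @slot trainKG \code{KnowledgeGraph} with held-out edges removed.
#' @slot valid data.frame of labelled validation pairs
#'   (\code{disease}, \code{drug}, \code{relation}, \code{label}).
#' @slot test data.frame of labelled test pairs, same columns.
#' @slot strategy one of \code{random_pair}, \code{zero_shot_disease},
#'   \code{disease_area}.
#' @slot heldDiseases character ids of diseases held out (empty for
#'   \code{random_pair}).
#' @slot spec list of the parameters the split was built with.
#'
#' @export
setClass("KGSplit",
  representation(
    trainKG = "KnowledgeGraph",
    valid = "data.frame",
    test = "data.frame",
    strategy = "character",
    heldDiseases = "character",
    spec = "list"
  )
)

#' Trained link-prediction model
#'
#' Bundles the trainable state of the encoder/decoder: initial node
#' embeddings, per-relation per-layer message weight matrices, and
#' per-relation DistMult decoder vectors, plus the (fixed) disease-pooling
#' operator when fine-tuned with augmentation.
#'
#' @slot nodeIds character, node ids in embedding row order.
#' @slot X numeric matrix (nodes x dim), initial embeddings.
#' @slot W list over relations of lists over layers of dim x dim matrices.
#' @slot decoder named list of per-relation decoder vectors w_r.
#' @slot relations character, relation vocabulary the encoder propagates.
#' @slot layers integer, number of message-passing layers L.
#' @slot dim integer, embedding dimension d.
#' @slot pooling list: \code{active} flag, sparse operator \code{P},
#'   gate values and the similarity table used to build it (empty when off).
#' @slot config list of training configuration actually used.
#' @slot history list of per-phase loss/metric traces.
#'
#' @export
setClass("RepurposeModel",
  representation(
    nodeIds = "character",
    X = "matrix",
    W = "list",
    decoder = "list",
    relations = "character",
    layers = "integer",
    dim = "integer",
    pooling = "list",
    config = "list",
    history = "list"
  )
)

#' Trained edge-masking explainer
#'
#' Amortised GraphMask-style gates: one single-layer network per
#' (relation, layer) scoring concatenated source/target messages, plus a
#' learnable per-(relation, layer) baseline vector substituted for dropped
#' messages, and the Lagrange-multiplier state of the constrained training.
#'
#' @slot Wg list over relations of lists over layers of length-2d weight
#'   vectors (plus scalar intercept stored as attribute).
#' @slot baseline list over relations of lists over layers of length-d
#'   baseline vectors b.
#' @slot bias numeric location bias added inside the sigmoid (3 at init).
#' @slot lambda numeric, final Lagrange multiplier (>= 0).
#' @slot relations character, gated relations.
#' @slot layers integer.
#' @slot history list with divergence/sparsity traces.
#'
#' @export
setClass("EdgeGates",
  representation(
    Wg = "list",
    baseline = "list",
    bias = "numeric",
    lambda = "numeric",
    relations = "character",
    layers = "integer",
    history = "list"
  )
)
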