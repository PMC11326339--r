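#' @include AllClasses.R
NULL

# canonical undirected key: endpoint ids sorted lexicographically + relation
canonicalEdgeKey <- function(idA, relation, idB) {
  lo <- ifelse(idA <= idB, idA, idB)
  hi <- ifelse(idA <= idB, idB, idA)
  paste(lo, relation, hi, sep = "\r")
}

#' Construct a knowledge graph from node and edge tables
#'
#' Edges are treated as undirected: an edge listed in both orientations is
#' kept once. Endpoints must exist in the node table.
#'
#' @param nodes data.frame with columns \code{id}, \code{type} and
#'   optionally \code{name}.
#' @param edges data.frame with columns \code{head_id}, \code{relation},
#'   \code{tail_id} (character ids).
#' @param nodeTypes,relationTypes optional declared vocabularies; default to
#'   the values observed in the tables.
#' @return A \linkS4class{KnowledgeGraph}.
#' @export
makeKG <- function(nodes, edges, nodeTypes = NULL, relationTypes = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$name)) nodes$name <- nodes$id
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      name = as.character(nodes$name),
                      stringsAsFactors = FALSE)
  if (is.null(nodeTypes)) nodeTypes <- sort(unique(nodes$type))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(relationTypes)) relationTypes <- sort(unique(as.character(edges$relation)))
  idx <- match(c(edges$head_id, edges$tail_id), nodes$id)
  if (anyNA(idx)) {
    bad <- unique(c(edges$head_id, edges$tail_id)[is.na(idx)])
    stopIfNot(FALSE, paste0("edge endpoint(s) not in node table: ",
                            paste(head(bad, 5), collapse = ", ")),
              class = "repurposeKG_validation_error")
  }
  n <- nrow(edges)
  ed <- data.frame(head = idx[seq_len(n)],
                   relation = as.character(edges$relation),
                   tail = idx[n + seq_len(n)],
                   stringsAsFactors = FALSE)
  # canonical orientation + dedup
  if (n) {
    hid <- nodes$id[ed$head]; tid <- nodes$id[ed$tail]
    flip <- hid > tid
    tmp <- ed$head[flip]; ed$head[flip] <- ed$tail[flip]; ed$tail[flip] <- tmp
    key <- canonicalEdgeKey(nodes$id[ed$head], ed$relation, nodes$id[ed$tail])
    ed <- ed[!duplicated(key), , drop = FALSE]
    rownames(ed) <- NULL
  }
  ed$head <- as.integer(ed$head); ed$tail <- as.integer(ed$tail)
  new("KnowledgeGraph", nodes = nodes, edges = ed,
      nodeTypes = nodeTypes, relationTypes = relationTypes)
}

#' Load a knowledge graph from an edge-list file
#'
#' Reads a TSV/CSV edge list with header columns \code{head_id},
#' \code{head_type}, \code{relation}, \code{tail_id}, \code{tail_type}
#' (extra columns ignored; common aliases such as \code{x_id}/\code{y_id}
#' are accepted). Undirected duplicates are collapsed. An optional node
#' table (\code{id}, \code{type}, \code{name}) supplies labels and catches
#' dangling endpoints.
#'
#' @param path edge-list file.
#' @param nodeTable optional path to a node table TSV.
#' @param nodeTypes,relationTypes optional declared vocabularies; when
#'   given, a value outside the vocabulary raises a parse error naming the
#'   offending line.
#' @param sep field separator; guessed from the file extension by default.
#' @return A \linkS4class{KnowledgeGraph}.
#' @export
loadKG <- function(path, nodeTable = NULL, nodeTypes = NULL,
                   relationTypes = NULL, sep = NULL) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  alias <- c(head_id = "x_id", head_type = "x_type", tail_id = "y_id",
             tail_type = "y_type", relation = "relation")
  for (col in names(alias)) {
    if (!col %in% names(df) && alias[[col]] %in% names(df))
      names(df)[names(df) == alias[[col]]] <- col
  }
  need <- c("head_id", "head_type", "relation", "tail_id", "tail_type")
  stopIfNot(all(need %in% names(df)),
            paste0("edge list must have columns: ", paste(need, collapse = ", ")),
            class = "repurposeKG_parse_error")
  # line numbers: +1 for header
  if (!is.null(relationTypes)) {
    bad <- which(!df$relation %in% relationTypes)
    if (length(bad))
      stopIfNot(FALSE, paste0("unknown relation '", df$relation[bad[1]],
                              "' at line ", bad[1] + 1L),
                class = "repurposeKG_parse_error")
  }
  if (!is.null(nodeTypes)) {
    bad <- which(!(df$head_type %in% nodeTypes & df$tail_type %in% nodeTypes))
    if (length(bad))
      stopIfNot(FALSE, paste0("unknown node type at line ", bad[1] + 1L),
                class = "repurposeKG_parse_error")
  }
  nodes <- unique(data.frame(
    id = c(as.character(df$head_id), as.character(df$tail_id)),
    type = c(as.character(df$head_type), as.character(df$tail_type)),
    stringsAsFactors = FALSE))
  stopIfNot(!anyDuplicated(nodes$id),
            "node id appears with more than one type",
            class = "repurposeKG_validation_error")
  if (!is.null(nodeTable)) {
    nt <- read.delim(nodeTable, sep = sep, stringsAsFactors = FALSE)
    stopIfNot(all(c("id", "type") %in% names(nt)),
              "node table must have columns id, type",
              class = "repurposeKG_parse_error")
    dangling <- setdiff(nodes$id, as.character(nt$id))
    stopIfNot(length(dangling) == 0,
              paste0("edge endpoint(s) missing from node table: ",
                     paste(head(dangling, 5), collapse = ", ")),
              class = "repurposeKG_validation_error")
    nodes <- data.frame(id = as.character(nt$id), type = as.character(nt$type),
                        name = if (is.null(nt$name)) as.character(nt$id)
                               else as.character(nt$name),
                        stringsAsFactors = FALSE)
  }
  makeKG(nodes,
         data.frame(head_id = df$head_id, relation = df$relation,
                    tail_id = df$tail_id, stringsAsFactors = FALSE),
         nodeTypes = nodeTypes, relationTypes = relationTypes)
}

#' Write a knowledge graph to an edge-list TSV
#'
#' Emits the canonical dialect read by [loadKG()]: header
#' \code{head_id, head_type, relation, tail_id, tail_type}, one undirected
#' edge per row, rows in canonical order.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param path output file.
#' @param nodeTable optional path for a companion node table TSV
#'   (\code{id, type, name}); required to round-trip isolated nodes.
#' @return \code{path}, invisibly.
#' @export
writeKG <- function(kg, path, nodeTable = NULL) {
  ed <- kg@edges; nd <- kg@nodes
  if (!is.null(nodeTable))
    write.table(nd, nodeTable, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- data.frame(head_id = nd$id[ed$head], head_type = nd$type[ed$head],
                    relation = ed$relation,
                    tail_id = nd$id[ed$tail], tail_type = nd$type[ed$tail],
                    stringsAsFactors = FALSE)
  out <- out[order(out$head_id, out$relation, out$tail_id), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn makeKG Number of nodes.
#' @export
nodeCount <- function(kg) nrow(kg@nodes)

#' @describeIn makeKG Number of (undirected) edges.
#' @export
edgeCount <- function(kg) nrow(kg@edges)

#' Accessors for knowledge-graph tables
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @return \code{kgNodes}: the node table. \code{kgEdges}: the edge table
#'   with character id endpoints. \code{relationTypes}/\code{nodeTypes}:
#'   declared vocabularies. \code{nodeIdsOfType}: ids of one node type.
#' @export
kgNodes <- function(kg) kg@nodes

#' @rdname kgNodes
#' @export
kgEdges <- function(kg) {
  ed <- kg@edges
  data.frame(head_id = kg@nodes$id[ed$head], relation = ed$relation,
             tail_id = kg@nodes$id[ed$tail], stringsAsFactors = FALSE)
}

#' @rdname kgNodes
#' @export
relationTypes <- function(kg) kg@relationTypes

#' @rdname kgNodes
#' @export
nodeTypes <- function(kg) kg@nodeTypes

#' @rdname kgNodes
#' @param type node type label.
#' @export
nodeIdsOfType <- function(kg, type) kg@nodes$id[kg@nodes$type == type]

#' Neighbours of a node under one relation
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param id node id.
#' @param relation relation label, or \code{NULL} for all relations.
#' @return Character vector of neighbour ids (each neighbour once per
#'   relation edge).
#' @export
neighborIds <- function(kg, id, relation = NULL) {
  i <- match(id, kg@nodes$id)
  stopIfNot(!is.na(i), paste0("unknown node id: ", id))
  ed <- kg@edges
  if (!is.null(relation)) ed <- ed[ed$relation == relation, , drop = FALSE]
  nb <- c(ed$tail[ed$head == i], ed$head[ed$tail == i])
  kg@nodes$id[nb]
}

# Directed view of one relation's edges: every undirected edge contributes a
# message in both directions. Returns data.frame(src, dst, edge) where `edge`
# is the row index into kg@edges (shared by the two directions).
directedEdges <- function(kg, relation) {
  ed <- kg@edges
  sel <- which(ed$relation == relation)
  data.frame(src = c(ed$head[sel], ed$tail[sel]),
             dst = c(ed$tail[sel], ed$head[sel]),
             edge = c(sel, sel))
}

# Mean-aggregation operators: named list of sparse N x N matrices A_r with
# A_r[j, i] = 1/|N_j^r| for every directed message i -> j.
relationAdjacency <- function(kg, relations = NULL) {
  if (is.null(relations)) relations <- relationTypes(kg)
  n <- nodeCount(kg)
  out <- lapply(relations, function(r) {
    de <- directedEdges(kg, r)
    if (!nrow(de)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                               x = numeric(), dims = c(n, n)))
    deg <- tabulate(de$dst, nbins = n)
    Matrix::sparseMatrix(i = de$dst, j = de$src, x = 1 / deg[de$dst],
                         dims = c(n, n))
  })
  names(out) <- relations
  out
}

# |N_i^r| for every node, summed over a set of relations
relationDegrees <- function(kg, relations) {
  n <- nodeCount(kg)
  deg <- integer(n)
  ed <- kg@edges[kg@edges$relation %in% relations, , drop = FALSE]
  if (nrow(ed)) deg <- tabulate(c(ed$head, ed$tail), nbins = n)
  deg
}

#' Summary statistics of a knowledge graph
#'
#' Counts nodes, edges, node and relation types, per-type and per-relation
#' breakdowns, and the fraction of disease nodes without any indication
#' edge (the zero-shot frontier of the graph).
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param diseaseType,indicationRelation labels used for the zero-indication
#'   statistic.
#' @return A list of counts.
#' @export
kgSummary <- function(kg, diseaseType = "disease",
                      indicationRelation = "indication") {
  nd <- kg@nodes; ed <- kg@edges
  diseases <- which(nd$type == diseaseType)
  withInd <- integer(0)
  sel <- ed$relation == indicationRelation
  if (any(sel)) withInd <- unique(c(ed$head[sel], ed$tail[sel]))
  zeroInd <- if (length(diseases))
    mean(!(diseases %in% withInd)) else NA_real_
  list(
    nNodes = nrow(nd),
    nEdges = nrow(ed),
    nNodeTypes = length(unique(nd$type)),
    nRelationTypes = length(unique(ed$relation)),
    nodesByType = table(nd$type),
    edgesByRelation = table(ed$relation),
    nDiseases = length(diseases),
    nDrugs = sum(nd$type == "drug"),
    nIndications = sum(sel),
    nContraindications = sum(ed$relation == "contraindication"),
    fracDiseasesZeroIndication = zeroInd
  )
}

#' Check a downloaded reference knowledge-graph file against its published
#' statistics
#'
#' For users who have obtained the published curated knowledge graph
#' edge-list file: loads it and compares node/edge/type counts and the
#' zero-indication disease fraction against the reference values.
#'
#' @param path path to the downloaded edge-list file.
#' @return A data.frame of statistic, observed and reference values with an
#'   \code{ok} flag per row.
#' @export
checkReferenceKGStats <- function(path) {
  kg <- loadKG(path)
  s <- kgSummary(kg)
  ref <- c(nNodes = 123527, nEdges = 8063026, nDiseases = 17080,
           nDrugs = 7957, nIndications = 9388, nContraindications = 30675,
           nRelationTypes = 29, fracDiseasesZeroIndication = 0.92)
  obs <- c(s$nNodes, s$nEdges, s$nDiseases, s$nDrugs, s$nIndications,
           s$nContraindications, s$nRelationTypes,
           round(s$fracDiseasesZeroIndication, 2))
  data.frame(statistic = names(ref), observed = obs, reference = unname(ref),
             ok = obs == unname(ref))
}

setMethod("show", "KnowledgeGraph", function(object) {
  s <- kgSummary(object)
  cat("KnowledgeGraph:", s$nNodes, "nodes,", s$nEdges, "edges\n")
  cat("  node types (", s$nNodeTypes, "): ",
      paste(names(s$nodesByType), s$nodesByType, sep = ":", collapse = ", "),
      "\n", sep = "")
  cat("  relation types:", s$nRelationTypes, "\n")
})
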