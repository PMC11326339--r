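# Independent brute-force oracles shared across test files.

# unrolls propagate / mean-aggregate / residual-update with explicit loops
unrolledEncode <- function(kg, X, W, L) {
  nd <- kgNodes(kg); e <- kgEdges(kg)
  H <- X
  for (l in seq_len(L)) {
    Hnew <- H
    for (j in seq_len(nrow(nd))) {
      for (r in names(W)) {
        er <- e[e$relation == r, , drop = FALSE]
        nbr <- c(er$tail_id[er$head_id == nd$id[j]],
                 er$head_id[er$tail_id == nd$id[j]])
        if (!length(nbr)) next
        msgs <- t(vapply(nbr, function(i)
          as.numeric(W[[r]][[l]] %*% H[match(i, nd$id), ]),
          numeric(ncol(X))))
        Hnew[j, ] <- Hnew[j, ] + colMeans(msgs)
      }
    }
    H <- Hnew
  }
  H
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins (R's tie convention: relative tolerance 1e-7)
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# O(n^2) threshold-sweep oracle for the step-wise PR curve
auprcOracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; area <- 0
  nPos <- sum(labels == 1)
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1); fp <- sum(labels[sel] == 0)
    area <- area + (tp / (tp + fp)) * (tp / nPos - prevRec)
    prevRec <- tp / nPos
  }
  area
}

# shared 1-hop neighbours of the four signature node types, from the edge
# table directly (independent of the signature machinery)
sharedNeighbours <- function(kg, d1, d2) {
  types <- c("gene/protein", "effect/phenotype", "exposure", "disease")
  nd <- kgNodes(kg)
  nb <- function(d) {
    ids <- neighborIds(kg, d)
    unique(ids[nd$type[match(ids, nd$id)] %in% types])
  }
  length(intersect(nb(d1), nb(d2)))
}

# recursive DFS enumerating simple paths of <= maxHops edges
simplePathsOracle <- function(edges, from, to, maxHops) {
  adj <- split(c(edges$tail_id, edges$head_id),
               c(edges$head_id, edges$tail_id))
  found <- list()
  walk <- function(node, path) {
    if (node == to) { found[[length(found) + 1]] <<- path; return() }
    if (length(path) >= maxHops) return()
    for (nxt in adj[[node]]) {
      if (nxt %in% c(from, path)) next
      walk(nxt, c(path, nxt))
    }
  }
  walk(from, character(0))
  found
}
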