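#' @include knowledge_graph.R
NULL

#' Generate a synthetic biomedical knowledge graph with planted treatment
#' rules
#'
#' Emulates the structure of curated medical knowledge graphs at desk
#' scale: five node types (gene/protein, disease, drug, effect/phenotype,
#' exposure) and eleven relation types. Diseases are organised into groups
#' that share a gene module and hallmark phenotypes (so signature
#' similarity is high within a group and low across groups), drugs target
#' genes drawn from one group's module, and a planted treatment rule makes
#' a drug an indication for a disease with probability increasing in the
#' overlap between the drug's targets and the disease's gene neighbourhood:
#' \deqn{P(indication) = s (1 - 0.5^{o})} with overlap \eqn{o} and rule
#' strength \eqn{s}. Contraindications are planted on zero-overlap drugs;
#' a smaller off-label set on remaining overlapping drugs.
#'
#' @param nDiseases,nDrugs,nGenes,nPhenotypes,nExposures node counts.
#' @param nGroups number of disease groups (>= 2).
#' @param treatRuleStrength rule strength \eqn{s} in (0,1]; at 1 every
#'   planted indication's drug shares at least one gene neighbour with its
#'   disease.
#' @param seed integer seed; output is fully determined by it.
#' @return list with elements \code{kg} (a \linkS4class{KnowledgeGraph})
#'   and \code{ledger}, a list recording group memberships, gene modules,
#'   disease gene sets, drug target sets and all planted treatment truths.
#' @export
simulateKG <- function(nDiseases = 200, nDrugs = 100, nGenes = 500,
                       nPhenotypes = 100, nExposures = 30, nGroups = 4,
                       treatRuleStrength = 1, seed = 1) {
  stopIfNot(all(c(nDiseases, nDrugs, nGenes, nPhenotypes, nExposures) > 0),
            "all sizes must be positive")
  stopIfNot(nGroups >= 2, "nGroups must be >= 2")
  stopIfNot(treatRuleStrength > 0 && treatRuleStrength <= 1,
            "treatRuleStrength must be in (0,1]")

  genes <- paste0("gene", seq_len(nGenes))
  diseases <- paste0("disease", seq_len(nDiseases))
  drugs <- paste0("drug", seq_len(nDrugs))
  phenos <- paste0("phenotype", seq_len(nPhenotypes))
  expos <- paste0("exposure", seq_len(nExposures))

  grp <- function(x) rep(seq_len(nGroups), length.out = length(x))
  geneGroup <- grp(genes); disGroup <- grp(diseases)
  drugGroup <- grp(drugs); phenoGroup <- grp(phenos); expoGroup <- grp(expos)
  byGroup <- function(x, g)
    split(x, factor(g, levels = seq_len(nGroups)))
  modules <- byGroup(genes, geneGroup)
  phenoPools <- byGroup(phenos, phenoGroup)
  expoPools <- byGroup(expos, expoGroup)
  stopIfNot(all(lengths(modules) > 0), "need at least one gene per group")
  # first 3 phenotypes of each pool are hallmark phenotypes of the group
  hallmarks <- lapply(phenoPools, function(p) head(p, 3))

  E <- list()
  addEdges <- function(h, r, t) {
    if (length(h))
      E[[length(E) + 1L]] <<- data.frame(head_id = h, relation = r,
                                         tail_id = t,
                                         stringsAsFactors = FALSE)
  }

  ledger <- list(seed = seed, nGroups = nGroups,
                 treatRuleStrength = treatRuleStrength,
                 diseaseGroups = stats::setNames(disGroup, diseases),
                 drugGroups = stats::setNames(drugGroup, drugs),
                 geneModules = modules)

  withSeed(seed, {
    # protein-protein interactions: enriched within modules + background
    for (g in seq_len(nGroups)) {
      mod <- modules[[g]]
      partner <- replicate(2, sample(mod, length(mod), replace = TRUE))
      addEdges(rep(mod, 2), "protein_protein", as.vector(partner))
    }
    addEdges(sample(genes, nGenes %/% 5, replace = TRUE), "protein_protein",
             sample(genes, nGenes %/% 5, replace = TRUE))

    # disease neighbourhoods
    diseaseGenes <- vector("list", nDiseases); names(diseaseGenes) <- diseases
    for (i in seq_len(nDiseases)) {
      g <- disGroup[i]
      own <- sample(modules[[g]], min(length(modules[[g]]), 8 + rpois(1, 3)))
      bg <- sample(genes, 1)
      diseaseGenes[[i]] <- unique(c(own, bg))
      addEdges(rep(diseases[i], length(diseaseGenes[[i]])), "disease_gene",
               diseaseGenes[[i]])
      ph <- unique(c(hallmarks[[g]],
                     sample(phenoPools[[g]], min(length(phenoPools[[g]]),
                                                 2 + rpois(1, 1)))))
      if (length(ph))
        addEdges(rep(diseases[i], length(ph)), "disease_phenotype", ph)
      if (length(expoPools[[g]]) && runif(1) < 0.3)
        addEdges(diseases[i], "disease_exposure", sample(expoPools[[g]], 1))
      sibs <- setdiff(diseases[disGroup == g], diseases[i])
      if (length(sibs))
        addEdges(rep(diseases[i], min(2, length(sibs))), "disease_disease",
                 sample(sibs, min(2, length(sibs))))
    }

    # drug neighbourhoods
    drugTargets <- vector("list", nDrugs); names(drugTargets) <- drugs
    for (j in seq_len(nDrugs)) {
      g <- drugGroup[j]
      tg <- sample(modules[[g]], min(length(modules[[g]]), 4 + rpois(1, 2)))
      if (runif(1) < 0.5) tg <- c(tg, sample(genes, 1))
      drugTargets[[j]] <- unique(tg)
      addEdges(rep(drugs[j], length(drugTargets[[j]])), "drug_gene",
               drugTargets[[j]])
      nSide <- min(2, nPhenotypes)
      addEdges(rep(drugs[j], nSide), "drug_phenotype", sample(phenos, nSide))
    }
    addEdges(sample(drugs, nDrugs %/% 2, replace = TRUE), "drug_drug",
             sample(drugs, nDrugs %/% 2, replace = TRUE))

    # planted treatment rules
    ind <- list(); contra <- list(); off <- list()
    for (i in seq_len(nDiseases)) {
      dg <- diseaseGenes[[i]]
      overlap <- vapply(drugTargets,
                        function(tg) length(intersect(tg, dg)), integer(1))
      pInd <- treatRuleStrength * (1 - 0.5^overlap)
      isInd <- runif(nDrugs) < pInd
      if (any(isInd))
        ind[[length(ind) + 1L]] <- data.frame(
          disease = diseases[i], drug = drugs[isInd],
          overlap = overlap[isInd], stringsAsFactors = FALSE)
      zero <- which(overlap == 0 & !isInd)
      if (length(zero)) {
        pick <- sample(zero, min(2, length(zero)))
        pick <- pick[runif(length(pick)) < 0.6]
        if (length(pick))
          contra[[length(contra) + 1L]] <- data.frame(
            disease = diseases[i], drug = drugs[pick],
            stringsAsFactors = FALSE)
      }
      rest <- which(overlap >= 1 & !isInd)
      if (length(rest)) {
        pick <- rest[runif(length(rest)) < 0.15]
        if (length(pick))
          off[[length(off) + 1L]] <- data.frame(
            disease = diseases[i], drug = drugs[pick],
            stringsAsFactors = FALSE)
      }
    }
    indications <- do.call(rbind, ind)
    stopIfNot(!is.null(indications) && nrow(indications) > 0,
              "configuration produced zero indications")
    contraindications <- if (length(contra)) do.call(rbind, contra) else
      data.frame(disease = character(), drug = character())
    offLabel <- if (length(off)) do.call(rbind, off) else
      data.frame(disease = character(), drug = character())
    addEdges(indications$disease, "indication", indications$drug)
    addEdges(contraindications$disease, "contraindication",
             contraindications$drug)
    addEdges(offLabel$disease, "off_label", offLabel$drug)

    ledger$diseaseGenes <- diseaseGenes
    ledger$drugTargets <- drugTargets
    ledger$indications <- indications
    ledger$contraindications <- contraindications
    ledger$offLabel <- offLabel
  })

  nodes <- data.frame(
    id = c(genes, diseases, drugs, phenos, expos),
    type = c(rep("gene/protein", nGenes), rep("disease", nDiseases),
             rep("drug", nDrugs), rep("effect/phenotype", nPhenotypes),
             rep("exposure", nExposures)),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, E)
  edges <- edges[edges$head_id != edges$tail_id, , drop = FALSE]  # no loops
  kg <- makeKG(nodes, edges)
  list(kg = kg, ledger = ledger)
}
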