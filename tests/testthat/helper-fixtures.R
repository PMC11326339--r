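# Shared fixtures, memoised so expensive objects build once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# hand-built toy graph: drug1 - gene1 - disease1 (+ an indication edge)
toyKG <- function(indication = TRUE) {
  nodes <- data.frame(
    id = c("drug1", "gene1", "disease1"),
    type = c("drug", "gene/protein", "disease"))
  edges <- data.frame(
    head_id = c("drug1", "gene1", if (indication) "drug1"),
    relation = c("drug_gene", "disease_gene", if (indication) "indication"),
    tail_id = c("gene1", "disease1", if (indication) "disease1"))
  makeKG(nodes, edges)
}

# small planted-structure synthetic graph for unit tests
smallSim <- function() {
  memo("smallSim", function()
    simulateKG(nDiseases = 60, nDrugs = 30, nGenes = 150, nPhenotypes = 45,
               nExposures = 15, nGroups = 3, seed = 7))
}

# a trained model on a random_pair split of the small graph
smallTrained <- function() {
  memo("smallTrained", function() {
    sim <- smallSim()
    sp <- makeSplit(sim$kg, "random_pair", holdoutFraction = 0.15, seed = 11)
    pm <- pretrainModel(sp@trainKG, d = 16, L = 2, epochs = 30, seed = 11)
    fm <- fineTuneModel(pm, sp, epochs = 120, patience = 25, seed = 11)
    list(sim = sim, split = sp, pretrained = pm, model = fm)
  })
}

# labelled query pairs (train positives + seeded negatives) on a split
labelledTrainPairs <- function(split, nMax = 200, seed = 5) {
  kg <- split@trainKG
  rows <- which(kg@edges$relation %in% c("indication", "contraindication"))
  rows <- head(rows, nMax)
  ed <- kg@edges[rows, , drop = FALSE]
  ty <- kg@nodes$type
  hd <- ty[ed$head] == "disease"
  pos <- data.frame(
    disease = kg@nodes$id[ifelse(hd, ed$head, ed$tail)],
    drug = kg@nodes$id[ifelse(hd, ed$tail, ed$head)],
    relation = ed$relation, label = 1L)
  neg <- sampleNegatives(pos, kg, perPositive = 1L, seed = seed)
  rbind(pos, neg)
}
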