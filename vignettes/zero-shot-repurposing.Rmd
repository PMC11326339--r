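---
title: "Zero-shot drug repurposing on a biomedical knowledge graph"
author: "repurposeKG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot drug repurposing on a biomedical knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposeKG)
```

## The problem

Most diseases — in curated medical knowledge graphs, the large majority —
have no approved drug. Standard drug-repurposing models are evaluated by
holding out a random subset of known drug–disease treatment pairs, a
setting in which the held-out disease usually still has *other* treatments
in training; models can then succeed by retrieving drugs similar to the
known ones. Zero-shot repurposing asks the harder question: predict
indications and contraindications for a disease with *no* treatment edges
observed during training.

`repurposeKG` implements a complete desk-scale system for this task: a
heterogeneous knowledge-graph data model, a relation-specific
message-passing encoder, a DistMult likelihood decoder trained with a
pre-train/fine-tune schedule, a degree-gated disease-similarity pooling
mechanism that transfers knowledge from well-annotated diseases to sparse
ones, a differentiable edge-masking explainer, the three evaluation split
strategies, explanation-fidelity metrics, and a log-odds-ratio enrichment
protocol against prescription/diagnosis records. Synthetic generators for
the knowledge graph and the patient cohort make every component exercisable
and testable without access to restricted data.

## Model

### Encoder

Every node $i$ receives an initial embedding $x_i \in \mathbb{R}^d$ drawn
Xavier-uniform (we use the convention $fan_{in}=fan_{out}=d$, so entries
are uniform on $[-\sqrt{3/d}, \sqrt{3/d}]$). Each of $L$ layers performs,
for every relation $r$:

1. *Propagate*: $m_{r,i}^{l} = W_r^{l} h_i^{l-1}$ — a relation-specific
   linear map of the source embedding; the message depends only on the
   source and is shared by all targets.
2. *Aggregate*: $\tilde m_{r,j}^{l} = |N_j^r|^{-1} \sum_{i \in N_j^r}
   m_{r,i}^{l}$ — the arithmetic mean over relation-$r$ neighbours. An
   empty neighbourhood contributes the zero vector, which preserves the
   residual identity below.
3. *Update*: $h_j^{l} = h_j^{l-1} + \sum_r \tilde m_{r,j}^{l}$.

The update equations contain no nonlinearity or normalisation between
layers and we implement them literally (an optional `tanh` flag exists for
experimentation, off by default). Defaults are $L = 2$ and $d = 128$; two
hops cover drug–gene–disease paths. All tests and the acceptance pipeline
run at $d = 32$, which is ample for the synthetic graph sizes used there.

### Decoder

For disease $i$, drug $j$ and treatment relation $r$ with trainable vector
$w_r$, the likelihood is the DistMult score through a logistic link:
$p_{i,j,r} = \sigma\!\big(\sum_d h_i \odot w_r \odot h_j\big)$, symmetric
in the two endpoints. Training minimises the mean binary cross-entropy
over positive pairs and sampled negatives, with probabilities clipped at
$10^{-7}$.

### Disease-similarity pooling

A disease's *signature* is the binary indicator of its 1-hop gene/protein,
effect/phenotype, exposure and disease neighbours; the dot product of two
signatures counts shared neighbours across those four types. For each
disease the $k = 5$ most similar diseases (ties broken by node id, self
excluded) are pooled with similarity-proportional weights into
$h^{sim}_i$, and the final embedding is the gated combination
$\hat h_i = c_i h^{sim}_i + (1 - c_i) h_i$ with
$c_i = 0.7\, e^{-0.7\,|N_i^r|} + 0.2$. The gate degree $|N_i^r|$ is the
disease's degree over treatment relations in the *training* graph, so
diseases with no known drugs get $c_i = 0.9$ (borrow heavily) while
well-annotated diseases approach the floor $0.2$. The printed equations
define an unnormalised dot-product similarity, which we use for ranking
and pooling weights; a cosine-normalised score is also reported for
diagnostics, since the two orderings can differ. Signatures, similarities
and gate degrees are computed on the training graph only, post split, to
avoid leaking held-out treatment edges.

Two degenerate cases are fixed by design: a disease whose retrieved
similar diseases all have score zero keeps its own embedding unchanged
(an identity row in the pooling operator, flagged to the caller) — a
zero-vector substitute would shrink precisely the diseases that simply
lack annotation; and $k$ is truncated with a warning when fewer other
diseases exist.

The whole mechanism is a fixed sparse linear operator $P$ applied to the
encoder output, so gradients flow through it end to end and the pooled
embeddings are recomputed at every forward pass rather than cached.

### Training schedule

*Pre-training* optimises the encoder and all per-relation decoder vectors
on link prediction across every relation type, treated equally, with
pooling off; every edge is visited each epoch and negatives are resampled
per epoch by type-consistent endpoint corruption filtered against known
edges. *Fine-tuning* re-initialises the treatment-relation decoder
vectors (avoiding negative transfer), activates pooling, and optimises
only the indication/contraindication/off-label objectives; the checkpoint
with the best validation AUPRC is kept, with early stopping at patience
10 (25 in the heavier test configurations). Because no printed values
exist for the optimiser, we use Adam with learning rates $10^{-3}$
(pre-train) and $5\times10^{-4}$ (fine-tune); all of this is configurable.
Validation and test negatives are sampled once per split under a fixed
seed (1:1 with positives) so that reported numbers are comparable across
runs; training negatives are resampled each epoch. Minibatches are edge
minibatches with full-graph message passing, which at desk scale is exact;
a subgraph-sampling variant would only matter at millions of edges.

No deep-learning framework is used: the encoder is linear in its
parameters layer by layer, so the package implements exact reverse-mode
gradients with sparse matrix algebra, and Adam, directly.

### Explainer

The explainer is an amortised edge-masking network in the GraphMask
style. For each relation and layer, a single-layer network scores the
concatenated source/target messages,
$\pi = \sigma(W_g [m_i \| m_j] + 3)$; the location bias of 3 keeps all
gates open at initialisation, so masked and unmasked predictions coincide
and sparsity is *learned*, not imposed. The hard decision
$z = \mathbb{1}[\pi > 0.5]$ is used in the forward pass, with a
straight-through estimator (logistic gradient) backward. A dropped
message is replaced by a learnable per-(relation, layer) baseline vector
rather than removed, keeping the mean aggregation well behaved. Training
solves
$\max_\lambda \min_{W_g} \sum \mathbb{1}[z \neq 0] +
\lambda(\|\hat p - p\|^2 - \beta)$
with the predictor frozen: gradient descent on the gate parameters
(sparsity enters the gradient through the soft $\pi$), projected ascent
on $\lambda \geq 0$ driven by the faithfulness constraint. The margin
$\beta$ is unprinted in the source material; we default to a mean squared
divergence budget of $0.03$ per query batch. Sparsity is emergent from
the $\beta$–$\lambda$ dynamics; there is no target-sparsity knob.

Edge importances are the pre-indicator gate values read off the masked
forward pass (the dynamics the gates were trained under), aggregated per
undirected edge by the maximum over layers and message directions — an
edge matters if any layer needs it; the mean is a documented alternative.
Explanations are all simple paths of at most 3 hops between the query
drug and disease through retained (importance $> 0.5$) edges, ranked by
the bottleneck score (minimum edge importance along the path): a path is
only as credible as its weakest link.

Fidelity metrics follow the masking semantics: *insertion* (performance
keeping only the top $K\%$ of edges), *deletion* (performance after
masking the top $K\%$) and the retained-versus-complement contrast
replace an excluded edge's messages with the learned baselines rather
than deleting the edge, because deletion changes the mean-aggregation
denominators and would conflate importance with renormalisation effects.
*Stability* perturbs the graph itself (removing a random 1–10% of edges)
and reports the Pearson correlation of importances.

## Evaluation splits

* `random_pair` — holds out `floor(fraction * n)` treatment edges
  uniformly; the conventional benchmark.
* `zero_shot_disease` — holds out a random disease subset with *all*
  their treatment edges; the defining property (zero treatment edges in
  train for every test disease) is asserted exhaustively in the tests.
* `disease_area` — holds out a named, biologically related disease set
  with all treatment edges, and additionally deletes a fraction
  (default 0.95) of those diseases' remaining non-treatment edges from
  training, emulating poorly characterised disease areas. The deleted
  fraction is not printed in the source material, hence configurable. An
  optional similarity-based exclusion of near-neighbour diseases is left
  off by default because no criterion or threshold is printed for it.

A validation fraction (default 5%) of the remaining training treatment
edges is carved out per split for model selection.

## Synthetic study conditions

The knowledge-graph generator emulates the structure that makes zero-shot
transfer possible in real curated graphs: 200 diseases in 4 groups, 100
drugs, 500 genes, 100 phenotypes, 30 exposures, 11 relation types. Each
group owns a gene module and hallmark phenotypes; diseases draw ~10 genes
from their group's module, drugs draw ~5 targets from one module, and a
planted rule makes a drug an indication with probability
$s(1 - 0.5^{o})$ in the target/disease-gene overlap $o$ (strength
$s = 1$ by default, so every indication shares at least one gene with its
disease). Contraindications are planted on zero-overlap drugs, a smaller
off-label set on remaining overlapping drugs. Group membership and every
planted truth are recorded in a ledger that the tests check against.

The EMR generator emulates a de-identified cohort (default 5,000
patients): diseases follow a skewed prevalence, drugs are prescribed at a
2% baseline rate, and drugs that are planted indications of a patient's
diseases are co-prescribed at a target odds ratio of 8 — the
co-prescription enrichment that the log-OR protocol is designed to
detect. Every patient has at least one diagnosis and one prescription.

What these generators do *not* emulate: ontology structure and hub
degree distributions of real curated graphs, literature biases, drug
combination effects, temporal structure in prescriptions, and
confounding by indication severity. Passing tests therefore demonstrate
that the machinery recovers planted structure under controlled
conditions, not clinical validity on real data.

## Numerical choices and edge cases

* Undirected edges are canonicalised (endpoint ids sorted) and
  deduplicated at load time; adjacency operators materialise both message
  directions.
* Empty neighbourhoods aggregate to zero; the empty graph encodes to the
  initial embeddings.
* BCE probabilities are clipped at $\varepsilon = 10^{-7}$.
* AUPRC is the step-wise (non-interpolated) area with tied scores grouped,
  matched against an exhaustive threshold-sweep oracle in the tests;
  AUROC uses the Mann–Whitney statistic with ties counted half.
* Fisher exact p-values are exact two-sided (hypergeometric tail
  summation); the odds-ratio point estimate is the sample $ad/bc$ with
  Haldane–Anscombe $+0.5$ on zero cells (estimate only, never the
  p-value); log-ORs use the natural log. Bonferroni correction caps at 1;
  the significance threshold is adjusted $p < 0.005$.
* Holdout counts round as `max(1, floor(fraction * n))`.
* All randomness is controlled by integer seeds; child seeds are derived
  arithmetically and stay below $2^{31}$.
* Ranking ties break by ascending node id everywhere.

## Problem sizes used in tests and the acceptance pipeline

Unit tests run on a 60-disease/30-drug graph with $d = 16$; the
acceptance pipeline runs the default 200-disease conditions with
$d = 32$, pre-training 60 epochs and fine-tuning up to 150 epochs with
patience 25, five seeds for the recovery and ablation comparisons, a
300-epoch explainer, and a 5,000-patient cohort with every held-out
indication disease as a query disease
for the enrichment buckets. These sizes were chosen so that planted
structure is comfortably recoverable while a full pipeline run remains a
desk-scale computation.

## Known limitations

* The encoder implements the printed linear update exactly; at much
  larger scale the lack of normalisation can make deep stacks drift, and
  the full-graph forward pass would need neighbour sampling.
* Amortised gates share parameters across edges of a relation/layer;
  per-query explainers would be sharper but are a different design.
* The EMR protocol measures co-occurrence, not prescription-for-
  indication linkage, and inherits all confounding of off-label use as a
  proxy label.
* Published headline numbers on the full curated knowledge graph
  (millions of edges, GPU training) are out of desk-scale reach; the
  package's claims are the property-level behaviours verified by its
  test suite on synthetic conditions.

## A worked example

```r
library(repurposeKG)

sim <- simulateKG(seed = 7)
split <- makeSplit(sim$kg, "zero_shot_disease", holdoutFraction = 0.1,
                   seed = 1)
pre <- pretrainModel(split@trainKG, d = 32, epochs = 60, seed = 1)
fit <- fineTuneModel(pre, split, epochs = 150, patience = 25, seed = 1)
evaluateSplit(fit, split)$auprc

disease <- split@test$disease[1]
head(predictRankedDrugs(fit, split@trainKG, disease), 5)

neg <- sampleNegatives(split@test, split@trainKG, seed = 41)
gates <- trainExplainer(fit, split@trainKG, rbind(split@test, neg))
imp <- edgeImportances(gates, fit, split@trainKG)
paths <- extractPaths(split@trainKG, imp,
                      drug = split@test$drug[1], disease = disease)
```

The README shows this pipeline with the numbers it printed.
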