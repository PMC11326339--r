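# repurposeKG

Zero-shot drug repurposing on heterogeneous biomedical knowledge graphs,
for computational drug-discovery researchers who need to predict
indications and contraindications for diseases with few or no known
treatments — and to explain those predictions.

## What it implements

Given a typed knowledge graph $G = (\mathcal V, \mathcal E,
\mathcal T_R)$ of genes/proteins, diseases, drugs, phenotypes and
exposures, the package learns node embeddings with an $L$-layer
relation-specific message-passing encoder

$$m_{r,i}^{l} = W_r^{l} h_i^{l-1}, \qquad
\tilde m_{r,j}^{l} = \tfrac{1}{|N_j^r|} \sum_{i \in N_j^r} m_{r,i}^{l},
\qquad h_j^{l} = h_j^{l-1} + \sum_r \tilde m_{r,j}^{l},$$

and scores a disease–drug pair under treatment relation $r$ with a
DistMult decoder, $p_{i,j,r} = \sigma(\sum h_i \odot w_r \odot h_j)$,
trained by binary cross-entropy with all-relation pre-training followed
by treatment-focused fine-tuning. Zero-shot generalisation comes from
degree-gated disease pooling: each disease's embedding is blended with a
similarity-weighted average of its $k$ most similar diseases (shared
1-hop gene/phenotype/exposure/disease neighbours), gated by
$c_i = 0.7 e^{-0.7 |N_i^r|} + 0.2$ so that sparsely annotated diseases
borrow heavily and well-annotated ones barely at all.

A GraphMask-style explainer learns per-edge gates (hard indicator
forward, straight-through backward, learnable baseline substitution,
Lagrangian sparsity/faithfulness trade-off) and exports ranked multi-hop
drug-to-disease explanation paths, with insertion/deletion/stability
fidelity metrics. An EMR module computes Fisher-exact log-odds-ratio
enrichment of predicted pairs in per-patient prescription/diagnosis
records with Bonferroni correction and top-1 / top-5 / top-5% /
bottom-50% bucket analysis. Seeded generators produce synthetic knowledge
graphs with planted treatment rules and synthetic patient cohorts with
planted co-prescription enrichment, so the whole pipeline is testable
end to end.

See `vignettes/zero-shot-repurposing.Rmd` for the model, its assumptions
and the design decisions.

## Worked example

```r
library(repurposeKG)

sim <- simulateKG(seed = 7)              # 930 nodes, ~7,800 edges
split <- makeSplit(sim$kg, "zero_shot_disease", holdoutFraction = 0.1,
                   seed = 1)
pre <- pretrainModel(split@trainKG, d = 32, epochs = 60, seed = 1)
fit <- fineTuneModel(pre, split, epochs = 150, patience = 25, seed = 1)
evaluateSplit(fit, split)$auprc
#> [1] 0.792122

disease <- split@test$disease[1]   # "disease7", zero treatment edges in train
head(predictRankedDrugs(fit, split@trainKG, disease), 3)
#>     drug likelihood rank
#> 1 drug79  0.9064078    1
#> 2 drug95  0.9063186    2
#> 3  drug3  0.8705182    3
```

Every test disease here had **zero** treatment edges during training; an
AUPRC well above the 0.5 chance level on balanced positives/negatives
means the model transfers treatment knowledge from similar diseases —
fine-tuning the same encoder without pooling scores lower (see the
acceptance output below). The ranking lists novel candidates (drugs
already linked to the disease are omitted) with their predicted
indication likelihoods.

Explanations for a prediction:

```r
neg <- sampleNegatives(split@test, split@trainKG, seed = 41)
gates <- trainExplainer(fit, split@trainKG, rbind(split@test, neg))
imp <- edgeImportances(gates, fit, split@trainKG)
mean(imp$retained)    # fraction of edges the model considers crucial
#> [1] 0.1302784
```

A thin CLI over the same functions lives at
`inst/scripts/repurposekg-cli.R` (`validate`, `synth`, `split`,
`benchmark`).

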