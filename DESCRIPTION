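Package: repurposeKG
Title: Zero-Shot Drug Repurposing on Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug indications and contraindications for diseases
    with few or no known treatments by link prediction on a heterogeneous
    biomedical knowledge graph. Implements a relation-specific
    message-passing encoder with mean aggregation and residual updates, a
    DistMult likelihood decoder trained with binary cross-entropy under an
    all-relation pre-training then treatment-focused fine-tuning schedule,
    degree-gated disease embedding augmentation driven by shared-neighbor
    disease signatures, a differentiable edge-masking explainer trained by
    Lagrangian relaxation that exports ranked multi-hop explanation paths,
    evaluation-split curation (random pair, zero-shot disease, disease
    area), ranking metrics, explanation-fidelity metrics (insertion,
    deletion, stability), and log-odds-ratio enrichment of predictions in
    prescription/diagnosis records. Includes seeded generators for
    synthetic knowledge graphs with planted treatment rules and synthetic
    medical-record cohorts with planted co-prescription enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'knowledge_graph.R'
    'disease_similarity.R'
    'emr_enrichment.R'
    'encoder.R'
    'splits.R'
    'predictor.R'
    'evaluation.R'
    'explainer.R'
    'simulate_kg.R'
    'utils.R'
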