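Package: mfpep
Title: Multi-Label Prediction of Multi-Functional Therapeutic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-label classification of short therapeutic
    peptides (5-50 residues) that may carry several functional annotations
    at once (antibacterial, anticancer, antifungal, ...). Implements a
    neural sequence classifier combining an embedding layer, multi-scale
    1-D convolutions, a bidirectional LSTM, multi-head self-attention and
    a sigmoid multi-label head, trained with a class-weighted binary
    cross-entropy in which the weight of class i is phi * log(N/n_i)^theta,
    designed for strongly imbalanced label distributions. Includes
    multi-label FASTA curation utilities, Chou-style multi-label evaluation
    metrics (precision, coverage, accuracy, absolute true, absolute false),
    repeated-subsample evaluation with significance testing, a motif-planted
    synthetic peptide generator with controllable class imbalance and label
    co-occurrence, and orchestration helpers for ensembling, grid-search
    cross-validation and ablation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
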