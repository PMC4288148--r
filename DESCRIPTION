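Package: enhancerEnsemble
Title: Two-Layer Ensemble Prediction of Enhancer Regions from Histone
    Marks or Sequence Composition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts enhancer regions from binned histone-modification
    ChIP-Seq signal (11 marks, 200 bp bins, per-dataset min-max scaling)
    or from 351 DNA sequence-composition attributes. Class imbalance is
    handled by partitioning training data into many learning subsets,
    each fitted with a Gaussian-kernel SVM tuned by a two-round grid
    search maximizing the geometric mean of sensitivity and specificity;
    committee vote fractions are aggregated by a small neural network (or
    majority vote) into a final call. Includes genome scanning, seeded
    synthetic-data generators for end-to-end testing, and base-pair
    overlap evaluation metrics (PPV, Jaccard, F1, promoter-overlap
    fraction) with multi-test rank aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
biocViews: FunctionalGenomics, GeneRegulation, Classification,
    SupportVectorMachine, Epigenetics, HistoneModification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
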