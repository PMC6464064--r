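Package: regcl
Title: Information-Dense Transcription Factor Binding Site Clusters for
    Regulatory Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An information-theoretic framework for dissecting promoter
    cis-regulatory architecture. Scores transcription factor binding sites in
    accessible promoter intervals with bit-valued position weight matrices
    (individual information R_i), groups sites into information-dense clusters
    (IDBC), converts cluster organization into fixed-length machine-learning
    features, labels transcription factor target genes from CRISPR and siRNA
    perturbation screens, predicts targets and genes with similar tissue-wide
    expression profiles (Bray-Curtis similarity), and re-evaluates promoters
    after in-silico single-nucleotide variants to report binding-site and
    cluster fates. Includes seeded synthetic-data generators with planted
    regulatory structure for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    e1071,
    jsonlite,
    methods,
    pROC,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    rpart,
    withr
Config/testthat/edition: 3
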