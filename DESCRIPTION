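Package: endmotif
Title: Self-Supervised Transformer Modelling of cfDNA End-Motif Rankings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models rankings of 5'-end k-mer motifs of cell-free DNA (cfDNA)
    fragments with a masked-language-model transformer encoder, and evaluates
    the learned representations for liquid-biopsy cancer classification.
    Provides end-motif counting from FASTQ/FASTA/SAM/BAM reads, ranked token
    sequence construction with corpus augmentation, a from-scratch transformer
    encoder with multi-head self-attention and a projection head, masked-token
    pretraining with a warmup-plus-cosine learning-rate schedule, linear
    probing of frozen CLS representations under stratified cross-validation
    with DeLong and Clopper-Pearson confidence intervals, CLS-attention motif
    importance analysis and attention networks, the motif diversity score
    (normalized Shannon entropy), the kBET batch-effect acceptance rate, and a
    Dirichlet-multinomial synthetic cohort generator so the whole pipeline is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    methods,
    purrr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
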