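Package: finecons
Title: Consensus Fine-Mapping of GWAS Loci with Context-Free and
    Tissue-Specific Functional Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative fine-mapping pipeline for common disease-associated
    variants. Expands queried GWAS loci into linkage-disequilibrium proxy sets
    from a phased haplotype reference panel, classifies variants against a
    refGene-style gene model (exonic, splicing, UTR, intronic, ncRNA, upstream,
    downstream, intergenic, with optional coding consequence), fits a
    semi-supervised elastic-net logistic model that anchors predictions for
    unlabeled variants to scores from a prior unsupervised method, aggregates
    context-free functional scores into an average ranking with permutation
    p-values, quantifies cross-method rank concordance, profiles per-tissue
    maximum scores, and prioritizes variants that stand in the top quantile of
    both a target-tissue score and a minimum fraction of context-free methods.
    Includes a synthetic-data module that emulates haplotype panels with block
    LD, toy gene models, correlated score matrices and sparse logistic training
    data so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
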