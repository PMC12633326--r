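Package: fitscape
Title: Multi-Environment Genomic Prediction and Interpretation of Yeast Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of colony fitness in diploid budding-yeast
    populations across multiple environments from three variant channels
    (biallelic SNPs, ORF presence/absence variants, and ORF copy-number
    variants). Implements the full analysis chain: variant filtering and
    dosage encoding, centered-IBS kinship, additive and dominance genomic
    relationship matrices, whole-genome regression (ridge-regression BLUP via
    spectral REML, BayesC and Bayesian LASSO Gibbs samplers), random-forest
    and gradient-boosting learners with exact tree-path Shapley attributions
    and pairwise Shapley interaction values, Gini-based nested-subset feature
    selection, additive+dominance REML heritability, SNP/ORF-to-gene mapping
    (genic intervals and reciprocal best match), Fisher-exact enrichment
    against curated benchmark fitness genes, cross-environment gene-sharing
    permutation tests, and a synthetic diploid cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    BiocGenerics,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
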