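Package: mirmednet
Title: Bayesian Network Screening of miRNA-Mediated Genetic Effects in
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects microRNA-mediated genetic effects on quantitative
    phenotypes in two-parent recombinant inbred panels. Strain distribution
    patterns (SDPs) obtained by collapsing completely linked SNPs are screened
    together with miRNA expression, gene expression and a phenotype for
    'cohesive' SDP-miRNA-gene-phenotype quadruples via pairwise Pearson
    correlation. Each quadruple is then evaluated by exhaustive BIC scoring of
    all admissible hybrid Gaussian Bayesian networks (binary SDP root,
    phenotype sink), with two BIC-difference decision steps for miRNA
    mediation and gene inclusion. Passing quadruples sharing a phenotype and a
    genomic locus are combined into larger networks learned by constrained
    hill-climbing with bootstrap model averaging, and fitted networks predict
    phenotype changes under quartile-scale interventions on miRNA or gene
    expression. A synthetic recombinant-inbred-panel generator with known
    causal ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
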