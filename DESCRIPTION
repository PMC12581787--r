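Package: panelcraft
Title: Targeted SNP Panel Design, Fingerprinting, Mixed-Model GWAS and
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building targeted-genotyping SNP panels from
    population variant data and exercising them downstream. Implements the
    panel-design funnel (site quality filters, flank and probe-window GC/N
    screening, k-mer seeded genome-uniqueness filtering, windowed LD pruning,
    linkage-map cross-referencing), minimal fingerprinting SNP sets by greedy
    set cover, population-genetic summaries (p-distance, neighbor-joining
    trees, PCA, nucleotide diversity, Weir-Cockerham FST), an EMMAX-style
    mixed-linear-model association scan with simple-matching kinship, and
    genomic prediction by GBLUP and the Bayes alphabet (BayesA/B/C Gibbs
    samplers) with repeated k-fold cross-validation, marker-density titration
    and GWAS-derived fixed-effect integration. A self-contained simulator
    generates genomes, structured genotypes and heritable phenotypes so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    Biostrings,
    vcfR,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
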