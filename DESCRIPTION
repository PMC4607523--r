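Package: sweepscan
Title: Selection Scans on Phased Population Genotypes with Empirical and
    Simulation-Based Calibration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects recent positive selection (selective sweeps) in phased
    human population genotype data. Implements gene-level diversity statistics
    (nucleotide diversity, Watterson's theta, Tajima's D), normalized Fay and
    Wu's H in sliding windows, per-SNP Weir-Cockerham FST, the derived
    intra-allelic nucleotide diversity (DIND) test with its sentinel rule for
    monomorphic derived classes, outgroup-parsimony polarization with ancient
    and archaic sample annotation, empirical calibration of every statistic
    against a control gene set with allele-frequency binning, coalescent
    simulation under multi-population demographies for DIND significance,
    joint decision rules that classify selection-target genes, and a gene-set
    resampling significance test. A built-in coalescent generator produces
    neutral and sweep-bearing synthetic datasets so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    GenomeInfoDb,
    jsonlite,
    rtracklayer,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
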