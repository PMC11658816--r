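Package: epicoord
Title: Higher-Order Coordination Analysis of DNA Methylation with Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify higher-order coordination in two-group DNA
    methylation array data. Differentially methylated positions (DMPs) are
    identified by per-probe linear modelling with Benjamini-Hochberg control,
    and differentially methylated regions (DMRs) by gap-constrained runs of
    DMPs scored against a group-label permutation null. Per-group hypergraph
    models are then built from DMP-by-CpG correlation matrices: correlations
    are binarized at a data-driven cut-off to form an incidence matrix whose
    product with its transpose counts shared correlations (hyperedge
    dimensions) between DMP pairs. Coordination is quantified by the Shannon
    entropy of the edge-dimension distribution, compared against random-CpG
    nulls and, at pathway level, by a Bayesian bootstrap comparison of
    entropy distributions. Indirect associations are separated from direct
    ones by global network silencing, with direct edges classified as cis or
    trans by genomic distance. A latent-factor simulator generates two-group
    methylomes with planted DMPs, DMR runs, and coordinated CpG blocks with
    full ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
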