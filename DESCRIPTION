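Package: exopattern
Title: Exome Variant Pattern Analysis for Small Familial Tumor-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing exome variant patterns between related tumor
    and control samples: normalized annotated-variant I/O (minimal VCF and
    ANNOVAR-style tables), per-sample variant class summaries, binary
    gene-affection matrices with non-metric multidimensional scaling and
    hierarchical clustering, a novelty-stratified transition/transversion
    editing-signature test, identity-by-state somatic variant inference
    against positive and negative control sets, interaction-network
    centrality, and hypergeometric gene-set over-representation with
    Benjamini-Hochberg false discovery control. Includes a pedigree-aware
    synthetic cohort generator with planted ground truth for method
    validation, and a pipeline driver that runs all stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vcfR,
    fgsea,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
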