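Package: methcrosstalk
Title: Cross-Talk Analysis of Rare Variants and DNA Methylation in Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for integrating rare-variant association
    with array-based DNA methylation in case-control studies of congenital
    heart disease and similar disorders. Provides carrier-based Fisher and
    gene-collapsing burden tests for rare damaging variants, empirical-Bayes
    moderated differential methylation on beta-value matrices with deltaBeta
    thresholding, three-criterion mutation-methylation integration (probe
    overlap, CpG-island variants, meQTL linkage), hypergeometric gene-set
    enrichment with Benjamini-Hochberg control, and protein-interaction
    network prioritization of candidates against a known disease-gene panel.
    A parameterized synthetic-cohort generator with recorded ground truth
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
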