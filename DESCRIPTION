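Package: ctmwas
Title: Cell Type-Specific Methylome-Wide Association Analysis from Bulk Blood Methylation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical deconvolution of bulk blood DNA methylation into cell
    type-specific phenotype associations. Estimates per-sample cell-type
    proportions from a reference panel by simplex-constrained least squares,
    tests cell type-specific associations with a continuous phenotype through a
    proportion-by-phenotype interaction regression after covariate
    residualization and principal-component confounder capture, combines
    cohorts by sample-size-weighted Stouffer meta-analysis with heterogeneity
    testing and false discovery rate control, performs gene-set enrichment of
    suggestive findings with a genomic circular-permutation null, and replicates
    discovery-significant sites across tissues with Bonferroni-adjusted
    look-ups. Includes a synthetic-data generator that emulates multi-cohort
    consortium studies with planted cell type-specific effects so the full
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
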