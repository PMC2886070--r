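Package: omicsconcord
Title: Cross-Omics Concordance Analysis for Spectral-Count Proteomics,
    Transcriptomics and Metabolite Chemotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying agreement between transcriptome,
    proteome and metabolome profiles of closely related species.
    Implements normalized spectral abundance factor (NSAF) quantitation
    from MS/MS spectral counts, per-gene linear-model and rank-based
    differential-expression calling with Benjamini-Hochberg adjustment,
    Spearman cross-layer correlation on a common locus set,
    size-corrected overlap statistics of regulated gene lists with a
    permutation null, Ward clustering of glucosinolate profiles,
    hydrolysis-product partitioning, and a rule engine that turns
    differential expression of glucosinolate-pathway loci into testable
    chemotype predictions. A synthetic multi-omics data generator with
    known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
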