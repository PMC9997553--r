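Package: winterGP
Title: Genomic Prediction of Winter Survivorship in Pedigreed Lowland Switchgrass
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction of winter
    survivorship and heading date in multi-generation lowland switchgrass
    pedigrees. Provides a pedigree/genome/phenotype simulator emulating a
    founder - F1 - sibling-mated pseudo-F2 - open-pollinated progeny design
    with depth-aware genotype calls; sliding-window grandparental-read
    haplotype reconstruction for shallow-sequenced pseudo-F2 individuals;
    marker filtering, unambiguous parental assignment, EM imputation and
    haplotype projection; realized additive, dominance and epistatic
    relationship matrices; multi-kernel average-information REML with
    year-specific residuals, BLUP/GEBV prediction, prediction error variance
    and reliability; two-stage weighted prediction; family- and
    generation-masked cross-validation; progeny prediction; and
    selection-response tools (selection intensity, breeder's equation,
    mid-parent heritability, inverted-density sampling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
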