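Package: dysbiome
Title: Meta-Analysis of Gut Microbiome Dysbiosis Across Chronic Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying dysbiosis in 16S rRNA OTU
    count data across chronic disease cohorts. Provides negative-binomial
    Wald differential-abundance testing with median-of-ratios depth
    normalization, subdivision of cohorts into independent populations with
    stochastic-label null groups, fold-difference summaries of OTU
    enrichment (loss- versus gain-of-function dysbiosis), genus-level
    presence matrices with multiscale-bootstrap cluster support (AU/BP),
    diversity-adjusted flagging of over-dysbiotic genera by the three-sigma
    rule, antibiotic-disease association via relative risk and Fisher's
    exact test, and weighted UniFrac beta diversity with PCoA and
    PERMANOVA. A synthetic cohort generator with known ground truth stands
    in for the original study data so every stage can be validated by
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    phyloseq
Config/testthat/edition: 3
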