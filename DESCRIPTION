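Package: pamuslink
Title: Paired TMT Proteome and RNA-Seq Transcriptome Analysis with
    emPAI/PAMUS Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies multiplexed tandem-mass-tag (TMT) proteomics
    experiments with the emPAI/PAMUS approach (in-silico tryptic
    digestion, protein abundance index, partitioning of emPAI across
    reporter channels, Mol% normalisation), calls differentially
    expressed proteins with exact or sampled permutation tests and
    Benjamini-Hochberg correction, and relates protein abundance to
    paired RNA-seq transcript abundance through three complementary
    analyses: fold-change correlation, a pooled linear mixed-effects
    model with per-culture random slopes, and per-gene regressions with
    a slope-sign census. Also summarises subcellular proteome
    remodeling by compartment and provides three gene-set enrichment
    statistics (logistic log-odds-ratio model, one-sided Fisher test,
    and a set-level t test on fold changes). Ships a synthetic-data
    generator for paired nutrient-deprivation studies with recorded
    ground truth, so every stage can be validated against known
    coupling structure, effect sizes and compartment shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    nlme,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
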