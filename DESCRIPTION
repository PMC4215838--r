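Package: EpibiontScreen
Title: Chemical Defence Screening of Algal Epibacterial Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links surface concentrations of macroalgal antifouling
    metabolites (DMSP, proline, fucoxanthin) to the composition of the
    host's epibacterial community. Provides rarefaction and relative
    abundance utilities around a SummarizedExperiment-derived OTU
    container, a within-treatment-level Spearman correlation screen with
    sign-consistency classification of OTUs into compound-positive,
    -negative and -neutral subgroups, clade-level odds-of-presence
    enrichment with pooled geometric means, confidence intervals and
    chi-squared tests, EC50-threshold defence-sufficiency assessment, the
    univariate treatment statistics (one-way ANOVA with assumption checks,
    Box-Cox, Tukey HSD letters, simple regression), and a synthetic
    community generator with known ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    MASS,
    car,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, Sequencing, StatisticalMethod
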