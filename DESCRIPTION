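Package: abatime
Title: ABA Time-Course Transcriptomics for Moss Diaspore Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for early abscisic acid (ABA) induced
    transcriptome dynamics in Physcomitrella patens protonema. Implements
    Bayesian-regularized (Cyber-T style) per-timepoint differential expression
    with Benjamini-Hochberg FDR, temporal response classification, nested
    polynomial time-course ANOVA with Storey q-values, a global
    subset-dynamics statistic combining mutual information and Pearson
    correlation distances to the whole transcriptome, sample-level PCA,
    cross-study set comparison with ortholog collapse, GO term enrichment by
    Fisher's exact test with Bonferroni correction, and a synthetic
    time-course generator with planted response archetypes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
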