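Package: syntropy
Title: Integrative Correlation Analysis of Paired Microbiome and Metabolome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of paired 16S microbiome and
    UPLC-MS metabolome profiles from the same subjects: inter-omic Spearman
    correlation networks with Storey q-value false-discovery control,
    WGCNA-style metabolite modules summarised by eigenmetabolites, global
    concordance testing by symmetric Procrustes and coinertia RV permutation
    tests, metabolite-driven microbial clustering with prediction-strength
    model selection, Kruskal-Wallis tests of imputed pathway differentiation,
    SparCC compositional correlation with permutation tests of
    metabolite-associated community structure, adduct-based putative
    metabolite identification within a ppm mass window, and cross-region
    metabolite matching. Includes a synthetic-data generator that plants
    every structure the pipeline is designed to recover, so all stages can
    be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    mclust,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
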