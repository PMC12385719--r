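Package: cottoneval
Title: Multivariate Evaluation and Elite Selection for Upland Cotton
    Germplasm Quality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multivariate evaluation of cottonseed nutritional
    and fiber quality across upland cotton (Gossypium hirsutum L.) germplasm
    panels: a fixed 34-trait registry (protein, oil, 16 amino acids, 8 fatty
    acids, 8 fiber traits), validated trait-table input/output, per-trait
    descriptive variation profiling with coefficients of variation, one-way
    ANOVA with Tukey HSD and compact letter displays across origin and
    breeding-period groups, full Pearson correlation matrices with
    significance stars, Ward hierarchical clustering of accessions, and a
    principal-component / fuzzy-membership-function (PCA-FMF) composite
    scoring model that ranks accessions and selects the top fraction as
    elite germplasm. A seeded synthetic-germplasm generator reproduces the
    reported statistical structure of a 259-accession panel (trait means,
    dispersions, a pinned correlation structure including the strong
    protein-oil trade-off, and additive origin and breeding-period effects)
    so the whole pipeline can be exercised and calibrated without access to
    per-accession data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
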