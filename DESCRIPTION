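Package: tillerqtl
Title: Augmented-Design Adjustment, Tillering Traits, and Association
    Mapping for Barley Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for quantitative genetics of tiller development
    in field-grown barley diversity panels: spatial adjustment of Type-2
    modified augmented designs (check-based Methods 1 and 3, check ANOVA,
    relative efficiency), broad-sense heritability from two-way ANOVA mean
    squares, tillering-rate and trajectory metrics with principal
    coordinates embedding, multiple-linear-regression variance partitioning
    by relative importance (lmg) with bootstrap stepwise selection and
    Cook's-distance pruning, linkage-disequilibrium background and decay
    estimation (Hill-Weir expectation), SNP filtering, LD-kNN imputation,
    greedy tagging and decay-distance thinning, a principal-component
    corrected single-marker association scan, and centimorgan-based QTL
    interval merging and overlap counting. Includes a seeded synthetic-data
    generator emulating the augmented field layout, map-distance-dependent
    linkage disequilibrium, and genetically structured tiller trajectories
    so the whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    car,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
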