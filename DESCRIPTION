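Package: mycoQTL
Title: Host-Genetics and Diet Effects on Gut Fungal and Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTL) for gut microbial
    and fungal abundances in multiparental advanced intercross line (AIL) mouse
    populations, and for the community-ecology statistics that accompany such
    studies. Includes a synthetic-data generator for four-founder AIL cohorts
    (haplotype mosaics, diet/sex/cage/generation structure, negative-binomial
    taxon counts with planted additive and interacting QTL), founder-haplotype
    reconstruction by hidden Markov model, kinship estimation from founder
    posteriors, variance-stabilized trait construction with mixed-model
    residualization, kinship-corrected additive and interaction LOD scans with
    permutation genome-wide thresholds and 1.5-LOD support intervals, variance
    decomposition, alpha/beta diversity with covariate adjustment, constrained
    ordination, differential-abundance and biomarker calls, indicator species
    analysis, and compositionality-aware (SparCC-style) inter-kingdom
    correlation networks with bootstrap significance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    lme4,
    vegan,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
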