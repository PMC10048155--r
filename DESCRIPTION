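Package: qpcrstab
Title: Reference-Gene Stability and Efficiency-Corrected RT-qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selection and validation of RT-qPCR reference genes for cell
    differentiation models. Screens candidate reference genes from proteome
    relative-abundance tables (one-way ANOVA and difference-of-means ranking),
    scores candidate stability with BestKeeper, NormFinder, geNorm (M values
    and pairwise variation V), and the comparative delta-Ct method, combines
    the per-algorithm ranks into a geometric-mean consensus, and quantifies
    target-gene expression with efficiency-corrected single reference-gene
    (Pfaffl) and multi reference-gene geometric-mean normalization. Includes
    standard-curve amplification-efficiency fitting, primer/amplicon QC
    arithmetic, and a seeded synthetic-data generator emulating a
    three-condition by three-replicate qPCR design for ground-truth recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
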