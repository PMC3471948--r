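Package: crossexpr
Title: Cross-Species Comparison of Stage-Wise Expression Changes in
    Preimplantation Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares gene expression between two species across
    preimplantation developmental stages (morula, blastocyst, inner cell
    mass) from summarized log2 expression matrices. Computes stage-wise
    log2 fold changes per species, selects genes by fold-change
    thresholds with three-set Venn overlaps, pairs fold changes across
    species through an ortholog translation table, classifies each
    ortholog pair as having a similar or different expression pattern
    using interval heuristics on the inter-species fold-change gap, and
    summarizes classifications over pathway and gene-family sets.
    Produces clustered heatmaps of top fold-change genes, cross-species
    fold-change scatterplots and per-gene expression profile plots. A
    seeded synthetic-data generator emulates the two-replicate,
    three-stage, two-species study design with planted concordant,
    discordant and species-specific genes so the full pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
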