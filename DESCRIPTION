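Package: beegut
Title: Absolute-Abundance Gut Microbiota and Physiology Analysis for Honey Bee Cage Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of pesticide effects on the honey
    bee gut microbiota and host physiology in factorial cage experiments.
    Converts qPCR quantification cycles into actin-normalized bacterial loads
    via plasmid standard curves, scales amplicon proportions into absolute
    ASV abundances, screens reagent contaminants against blank extractions,
    and provides from-scratch permutational multivariate statistics
    (PERMANOVA, ANOSIM, PERMDISP), Bray-Curtis and UniFrac dissimilarities,
    principal coordinate analysis, per-ASV permutation ANOVA with Tukey post
    hoc tests, physiological-marker statistics with normality routing,
    control-normalized UPGMA clustering, and Kaplan-Meier survival with
    log-rank tests. Includes a synthetic-data generator emulating a
    2 colonization x 5 pesticide cage design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    survival,
    phyloseq
Config/testthat/edition: 3
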