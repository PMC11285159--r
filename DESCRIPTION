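Package: poolsex
Title: Sex Chromosome Discovery from Pooled Sequencing and Turnover Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies sex chromosomes from male/female pooled whole-genome
    sequencing data. Computes per-site FST between the sex pools, classifies
    XY- and ZW-patterned SNPs from pool allele frequencies, aggregates them
    into 100-kb genome-scan windows with top-window selection and
    Kruskal-Wallis/Dunn rank tests, and detects shared origins of syntenic
    sex systems through sex-specific k-mer comparison across populations.
    Also provides clade-level statistics of sex chromosome recruitment: a
    Poisson fit with chi-square goodness of fit, a chromosome-size-weighted
    Monte Carlo null with Bonferroni correction, and turnover-rate estimation
    from phylogenetic branch lengths. A synthetic pool-seq generator with
    plantable sex-determining regions makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
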