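Package: apa3utr
Title: Alternative Polyadenylation Analysis of the SERPINA1 3'UTR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies alternative polyadenylation (APA) in the SERPINA1
    3'UTR from per-base RNA-seq coverage using a length-normalized distal
    ratio, and compares the ratio across cohorts, genotypes, GOLD stages,
    subcellular fractions and single-cell clusters. Annotates cleavage sites
    called from 3'-end sequencing counts with polyadenylation-signal
    hexamers, downstream G/U-rich elements and the bipartite QKI motif.
    Fits a no-intercept linear model of deletion-construct reporter
    luminescence to estimate per-region translation coefficients, scores
    RNA-binding proteins by a two-dimensional volcano effect statistic
    combining shRNA knockdown distal ratios with COPD differential
    expression, and summarizes RNA structure probing data (SHAPE reactivity
    classes, Shannon entropy of base-pairing probabilities). Ships seeded
    synthetic-data generators with planted truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
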