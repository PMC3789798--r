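Package: linkmapr
Title: Genetic Linkage Maps and Recombination Hotspots from Synthetic
    Genetic Array Colony Sizes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates meiotic recombinant fractions and genetic distances
    from normalized single- and double-mutant colony sizes produced by
    synthetic genetic array (SGA) screens in budding yeast, using the
    Haldane mapping function. Builds binned per-chromosome genetic linkage
    matrices, derives recombination-rate profiles and calls recombination
    hotspots, quantifies pericentric crossover suppression from cis/trans
    gene pairs, hotspot sets and classical genetic maps, and measures
    DSB-repressed region widths and centromeric cohesin peak widths from
    genomic tracks. Ships a synthetic-data generator with known ground
    truth (crossover-rate maps with hotspots and size-coupled pericentric
    suppression) so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
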