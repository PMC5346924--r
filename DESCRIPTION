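Package: fragpattern
Title: Enumerative Fragmentation Pattern Spaces for Unbiased RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models unbiased RNA-seq fragmentation as exhaustive placement of
    fragments on a single transcript. Enumerates and counts all fragmentation
    patterns exactly by dynamic programming, computes expected starting-point,
    fragment and read coverage profiles for single or ranged fragment lengths,
    optionally weighted by an empirical insert-length distribution derived from
    paired-end alignments. Includes a seeded simulator of fragmentation, PCR
    amplification and sequencing, and an estimator of the original number of
    transcript molecules based on distances between empirical cumulative
    distribution functions of starting-point profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
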