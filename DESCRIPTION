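Package: asartools
Title: Transcribed-Locus Calling, eCLIP Window Enrichment and Replication-Timing Asynchrony
Version: 0.1.0
Authors@R: person("ASAR", "Tools Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate ASAR loci (very long,
    strand-specific, contiguously transcribed intergenic RNAs) from stranded
    read intervals by two-stage gap merging with a 50 kb length cutoff; scoring
    eCLIP enrichment over size-matched input controls in 10 kb windows via a
    log2-ratio z-score with Benjamini-Hochberg FDR control; filtering
    ENCODE-style narrowPeak eCLIP peaks and locating RBP-dense subdomains; and
    quantifying replication-timing asynchrony between chromosome homologs from
    BrdU area-by-intensity measurement tables with a tie-corrected
    Kruskal-Wallis test. Ships a synthetic-data generator with ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
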