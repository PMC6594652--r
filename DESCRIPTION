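Package: lsrseq
Title: Calling, Classifying and Quantifying Immunoglobulin
    Switch-Junction Amplicon Reads
Version: 0.1.0
Authors@R:
    person("lsrseq", "developers", email = "lsrseq-dev@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises recombination junctions between the
    immunoglobulin heavy-chain Smu donor region and downstream acceptor
    regions (switch regions or the 3' regulatory region super-enhancers)
    from amplicon sequencing reads.  Provides seed-and-extend local
    alignment of reads against reference windows, junction assembly with
    blunt/microhomology/insertion classification, deduplication to unique
    junctions with per-million normalisation, breakpoint-to-motif distance
    statistics against an exact random-break null (AID WRCY/RGYW hotspots,
    APOBEC3 TC/GA sites, G4Hunter G-quadruplex tracts, direct/inverted
    repeats), and a fully seeded amplicon read simulator with a truth
    table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
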