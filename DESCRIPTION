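Package: insertra
Title: Mapping Transgene Insertions in Repetitive Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for characterizing semi-random
    transposon (piggyBac-style) transgene insertions that land in highly
    repetitive genomic regions. Provides a forward simulator for
    multi-chromosome host genomes with planted repeat families, heterozygous
    TTAA-target-site insertions and Illumina-like / Nanopore-like reads; a
    self-contained seed-and-extend read mapper and local similarity search;
    junction evidence extraction (split reads, discordant pairs, flank
    consensus, target-site-duplication calls); read-depth copy-number
    estimation against single-copy reference loci; in-silico restriction
    digestion, Southern probing, inverse PCR and dot plots; and a locus
    resolver that ranks candidate insertion sites and integrates long-read
    contigs to break repeat-induced ambiguity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
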