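Package: intsitepref
Title: Genome-Wide Integration-Site Preference Analysis for Transposons
    and Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising where transposons (Ac/Ds, Tol2,
    Sleeping Beauty, piggyBac) and retroviruses (MMLV, MMTV) integrate in a
    genome.  Implements fragment-count filtering of putative insertion
    sites from linker-mediated PCR sequencing, generation of matched
    random control sets (uniform and restriction-site-distance matched),
    bootstrap empirical enrichment statistics against arbitrary feature
    tracks, gene-region and metagene profiling, aggregated target-site
    motif matrices, and dinucleotide step-parameter (DNA flexibility)
    profiles around integration sites.  A synthetic-data module generates
    genomes, gene models, expression tables and integration-site sets with
    planted, parameterised biases so that every pipeline stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
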