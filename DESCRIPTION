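Package: exshuffle
Title: Exon Shuffling Signals and Protein-Protein Interaction Network Topology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies protein-coding genes by evidence of exon shuffling
    (intron-flanked homologous regions between non-homologous genes) and
    relates the resulting ES/SS/WS gene categories to protein-protein
    interaction (PPI) network topology. Provides readers for protein FASTA,
    intron tables, BLAST tabular alignments, MITAB-style interaction records,
    Pfam-style domain hits and domain-domain interaction tables; a Smith-Waterman
    local alignment front end with Karlin-Altschul e-values; PPI network
    construction with detection-method filters, gene-level vertex collapsing
    and orthology projection; paralog family detection with a transitive
    70 percent added-HSP rule, paralog confluence and 1/k domain weighting;
    continuity-corrected chi-square, Mann-Whitney and resampling tests with
    optional protein-length matching; and a seeded synthetic-data generator
    that plants shuffling events and degree-structured networks so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
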