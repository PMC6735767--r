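Package: triplexscreen
Title: Promoter Screening for lncRNA Triplex Target Sites and Candidate
    Gene Nomination
Version: 1.0.0
Authors@R:
    person("Milo", "Fenner", email = "milo.fenner@example.org",
           role = c("aut", "cre"))
Description: Nominates candidate target genes of a chromatin-associated long
    noncoding RNA (lncRNA) from its DNA binding motif. Implements
    partial-match screening of promoter sequences for contiguous sub-words
    of a binding motif and its reverse complement, annotation of
    chromatin-isolation (ChIRP) fragments with signed distance to the
    nearest transcription start site, intersection of motif-positive
    promoters with differential-expression thresholds to rank candidate
    genes, and melting-temperature (Tm) shift estimation from fluorescence
    melting profiles as used to support RNA-DNA triplex formation. Ships a
    synthetic-data generator with exact ground truth so every stage is
    testable without external downloads, plus a command-line interface for
    the end-to-end screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
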