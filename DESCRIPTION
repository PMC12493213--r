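Package: asodesign
Title: Antisense Oligonucleotide Design and Duplex Property Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale pipeline for antisense oligonucleotide (ASO) design
    from a target gene or pre-mRNA sequence. Enumerates candidate ASOs by a
    sliding window, computes melting temperatures by the nearest-neighbor,
    basic and salt-adjusted methods for DNA/DNA, RNA/RNA, RNA/PS-RNA and
    RNA/2'OMe-RNA duplexes, assesses target-site accessibility from secondary
    structure ensembles, annotates splice-site masking from donor/acceptor
    probability tracks, evaluates ASO self-folding, screens off-targets with
    a built-in exhaustive scanner or BLASTn, and writes TSV/BED/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
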