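Package: circProbe
Title: Host-Exclusion Design of Circular Probes for Rolling Circle
    Amplification Assays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs padlock-style circular DNA probes for rolling circle
    amplification (RCA) detection assays. Builds an exact-membership bitmap
    index over every 16-mer of a host transcriptome (2-bit encoded, one
    presence bit per possible 32-bit code, 512 MB regardless of the number
    of sequences), screens candidate 20-mer target sites so that none of
    their five constituent 16-mers occurs in the host, applies GC content,
    annealing temperature, 3'-end and homopolymer composition filters,
    validates head-to-tail junction 16-mers, selects four sites evenly
    distributed along the target, and assembles the 80-nt circular probe
    together with its reverse complement and per-arm reverse complements.
    Includes a seeded synthetic fixture generator with planted shared
    16-mers, a nucleotide quantity conversion (micrograms per millilitre to
    picomoles per microlitre), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
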