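Package: plastidkmer
Title: Kmer-Based Detection and Alignment-Free Phylogenetics for
    Chloroplast Genomes in Shotgun Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying a target plant chloroplast genome
    (plastome) inside complex shotgun read mixtures using exact kmer
    matching against a reference database of labeled genomes, including
    take-one-out cross-validation and spike-in dilution series for limit
    of detection. Also provides alignment-free D2 and D2* kmer distances
    with neighbor-joining tree reconstruction and outgroup rooting, a
    column-scan SNP/indel screen over whole-genome alignments, and a
    synthetic-data generator (circular genomes at controlled divergence,
    fixed-length reads with a substitution error model, and designed
    read mixtures) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    ape,
    phytools,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
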