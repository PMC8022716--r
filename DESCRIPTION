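Package: chiscan
Title: Detection of Chi-Like Recombination Motifs in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection of Chi-like DNA motifs (RecBCD recombination
    hotspots) in bacterial genomes. Scores octamer overrepresentation in
    (pseudo-)core genomes against Markov null models of orders 0-5 using a
    parametric-bootstrap Gaussian statistic, tests replication-strand
    polarization of genomic occurrences with a rank-sum test, builds
    pseudo-core genomes from best-reciprocal-hit orthologs of the two closest
    relatives, expands and characterizes candidate motif neighborhoods, maps
    motif presence/absence onto a phylogeny by parsimony, and simulates
    Markov-background genomes with planted polarized motifs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
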