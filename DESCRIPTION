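Package: syntenyanchors
Title: Annotation-Free Synteny Anchor Detection from k-mer Rareness Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genome-wide synteny anchors without gene annotation.
    Candidate anchor windows are selected per genome by aggregated k-mer
    occurrence counts (exact and with up to two mismatches), their
    within-genome uniqueness is quantified by local alignment and collinear
    chaining against the genome with the candidate excised, and candidates
    are matched across genomes under score thresholds that provably imply
    reciprocal-best anchor matches. Pairwise anchors are consolidated into
    multi-genome clusters with transitivity and reciprocal-best consistency
    audits. Includes a synthetic-genome simulator with exact truth maps for
    end-to-end validation, and exporters for BED and MCScanX-style inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
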