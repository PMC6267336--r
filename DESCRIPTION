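Package: mitorecomb
Title: Structural Variation and Repeat-Mediated Recombination in Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the structural dynamics of plant
    mitochondrial genomes from long reads: detection of dispersed repeats
    on circular genomes, construction of the master and alternative genome
    conformations implied by repeat-mediated homologous recombination,
    estimation of per-repeat recombination frequency from Oxford
    Nanopore-like long reads, pan-mitogenome core/variable/specific
    fragment classification with accumulation curves, depth-validated gene
    presence/absence calling, plastid-derived fragment and ORF detection,
    and genome-constitution statistics including parsimony-informative
    character counts.  A synthetic-data generator (circular genomes with
    planted dispersed repeats, plastid-derived insertions and genes;
    ONT-like long reads drawn from a mixture of conformations; evolved
    genome families) makes the whole pipeline testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
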