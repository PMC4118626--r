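Package: saltmir
Title: Small RNA Sequencing Analysis of Salt-Stress MicroRNA Responses
Version: 0.1.0
Authors@R: person("saltmir", "maintainers", email = "saltmir@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for plant small RNA sequencing studies of
    abiotic stress: FASTQ cleaning and tag collapsing, perfect-match genome
    annotation with hierarchical category assignment, minimum-free-energy
    hairpin folding, reference-guided (conserved) and genome-guided (novel)
    microRNA discovery with miRNA* duplex evidence, mismatch-limited plant
    target prediction, and Audic-Claverie exact-test differential expression
    between libraries with reads-per-million normalization. Includes a
    synthetic-data generator that emulates a four-library treatment/control
    leaf/root design with planted miRNA loci and fold-changes, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
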