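Package: tdnascreen
Title: Whole-Genome Sequencing Screen for Unintended Transgene Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes unintended insertions of plant
    transformation vector sequence in a transgenic genome by comparative
    whole-genome resequencing of the transgenic line and its non-transgenic
    wild type. Reads are filtered for exact vector 20-mers passing a base
    quality threshold, assembled with a keep-all-reads overlap-layout-consensus
    assembler, typed by per-base coverage in both genotypes, and classified by
    a five-step triage into the known T-DNA insertion, shared sequence,
    reference-genome matches, underrepresented contigs, contaminations, and
    candidate insertions requiring wet-lab confirmation. A synthetic-data
    module simulates a diploid host, a circular binary vector, a single T-DNA
    integration with a small host deletion, paired-end sequencing experiments,
    endophyte-like contamination and chimeric library artifacts, with
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
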