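Package: longstr
Title: Sequence-Based Forensic STR Profiling from Long Reads
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds sequence-based short tandem repeat (STR) allele catalogs
    from GenBank-style records, assigns noisy long (nanopore) reads to
    candidate alleles by semi-global edit distance, calls autosomal genotypes
    and Y haplotypes from read counts normalized to the best-covered allele,
    and reports profiles in both sequence-based (bracketed repeat motif) and
    CE-compatible length-based forensic nomenclature. Includes a profile
    concordance benchmarker (precision/recall/F1 at the allele level) and a
    seeded amplicon read simulator with configurable substitution/indel error
    rates and PCR stutter, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
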