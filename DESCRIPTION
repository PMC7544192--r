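Package: plascheck
Title: De Novo Plasmid Assembly Verification and Contamination Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence verification of small circular plasmids from Illumina
    paired-end reads without a reference. Implements strict mean-quality read
    filtering with coverage capping, a de Bruijn graph assembler tuned for
    plasmid-scale circular contigs, rotation- and strand-invariant comparison
    of circular sequences, and a reference-agnostic contamination statistic
    based on exact back-mapping of distinct filtered reads to the assembly,
    with logistic calibration of a contamination probability. Includes an
    Illumina-like read simulator and a contamination-spiking experiment
    harness for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    withr,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
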