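Package: duplexr
Title: Duplex-UMI Sequencing Simulation, Consensus Calling and
    Low-Frequency Edit Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for detecting and quantifying small genome-editing
    mutations (SNVs and short InDels) at allele fractions down to 0.1
    percent with duplex unique-molecular-identifier (UMI) sequencing.
    Includes a synthetic duplex-library simulator with explicit artefact
    classes (single-strand damage, end-repair damage, PCR jackpots),
    UMI/strand-tag extraction and primer-based locus assignment, glocal
    alignment to target windows, single-strand and duplex consensus
    building with N-masking of discordant positions, replicate-aware
    variant filtering with PAM-proximity annotation, and performance
    statistics (CV/bias against ENGL acceptance criteria, quasi-binomial
    linearity, Poisson regression with offsets, read down-sampling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
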