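Package: hzscan
Title: Locating Hybrid Incompatibility Loci from Hybrid-Zone Genome Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect Bateson-Dobzhansky-Muller hybrid
    incompatibilities from genome sequences sampled in a hybrid zone.
    Includes an individual-based forward simulator of a two-source /
    hybrid-sink population system with two-locus epistatic viability
    selection, a windowed site-frequency-spectrum (SFS) scan that scores
    every genomic window by the multinomial probability of its local SFS
    given the genome-wide SFS, bootstrap-calibrated two-threshold outlier
    calling, and the power / false-positive evaluation harness (constrained
    grid search over the calling thresholds and cross-validation) used to
    tune the scan.  Phased VCF input and output with ancestral-allele
    polarization is provided for application to empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
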