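Package: tilecall
Title: Physical-Model-Based Substitution Calling for High-Density Tiling
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single-nucleotide substitutions from high-density
    resequencing (tiling) microarray intensities using a finite-hybridization
    thermodynamic model of probe signal.  The model combines position-weighted
    nearest-neighbor (triplet) free energies for specific and non-specific
    binding, per-mismatch energy penalties, and probe self-folding, and is
    fitted to reference-sample intensities by a seeded population search.
    Substitutions are called by screening running-average residuals of
    mutant/reference log-intensity ratios and maximizing a log-likelihood
    ratio over candidate regions.  Includes a 1-bp tiling array designer
    (perfect-match plus central-base mismatch probes), a seeded forward-model
    simulator with implanted substitutions and deletions, and evaluation
    utilities (truth-set filtering, call matching, sensitivity curves,
    threshold selection).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
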