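Package: peptigen
Title: Peptidogenomic Identification and Quantitation of Disulfide-Rich Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying and quantifying intact disulfide-rich
    peptides, built around the canine (Canidae) hepcidin-25 hormone.
    Covers disulfide-aware elemental composition and monoisotopic mass
    calculation, isotope-envelope prediction and multi-charge m/z algebra,
    charge-state deconvolution, cysteine-corrected b/y fragment-ion
    prediction and MS/MS annotation, candidate-sequence ranking against
    observed spectra, nucleotide translation and degenerate
    reverse-translation searches with exon-split coding-match discovery,
    ortholog conservation analysis, and internal-standard LC-MS
    quantitation with a Friedman time-course test. A synthetic-data
    module generates spectra, genomes, calibration series and
    time-courses with known ground truth so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
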