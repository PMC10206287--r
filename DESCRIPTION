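Package: chromeval
Title: Chromatographic Peak Evaluation, Mobile-Phase Scoring and
    Retention-Time Library Construction for LC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts per-analyte ion chromatograms from LC-MS runs in
    mzML or mzXML format, corrects baselines by asymmetric iteratively
    reweighted penalized least squares and smooths with a Savitzky-Golay
    filter, detects chromatographic peaks and quantifies their quality
    with eight metrics (mass chromatographic quality, maximum intensity,
    retention-time RSD over replicate injections, standard-over-blank
    ratio, jaggedness, asymmetry factor, FWHM and modality). Mobile
    phases are compared by a rank-based peak quality score combining
    validated-peak counts with an ANOVA-gated asymmetry rank, and
    replicate standard injections are distilled into a validated
    retention-time reference library. Includes a synthetic-data
    generator that writes standards-conformant mzML/mzXML with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    signal,
    Matrix,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
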