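Package: msidiscrim
Title: Discrimination of Tissue Regions in MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("MSI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating cancerous from normal
    tissue in MALDI mass spectrometry imaging (MSI) data, in the tryptic
    peptide and lipid domains. Provides spectra preprocessing (resampling,
    adaptive baseline correction, TIC-based outlier screening, FFT alignment,
    TIC normalization), Gaussian mixture modelling of the average spectrum
    with component filtering, isotope-envelope merging and per-pixel
    quantification, divisive k-means image segmentation with a dip-test
    stopping rule, robust differential statistics (Mann-Whitney U with
    Benjamini-Hochberg control, trimmed/Winsorized Cohen's d), a
    BIC-guided logistic classifier with multiple-random-validation feature
    scoring, and mass-based annotation of components against candidate
    peptide and lipid lists. A synthetic phantom generator with planted
    ground truth makes every stage testable without real tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
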