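Package: egfoglc
Title: Mapping and Quantifying O-Glucosylation of EGF Repeats from LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for site mapping and stoichiometry analysis of
    POGLUT2/POGLUT3-mediated O-glucosylation (and associated beta-hydroxylation)
    of EGF repeats in extracellular matrix proteins such as the fibrillins and
    latent TGF-beta binding proteins. Provides EGF-repeat annotation and
    cysteine-spacing detection on protein sequences, consensus-sequence site
    prediction with the original, revised and broad search patterns, in-silico
    protease digestion and theoretical glycopeptide mass/charge computation for
    the four glycoforms (unmodified, +hydroxyl, +hexose, +hexose+hydroxyl),
    extracted-ion-chromatogram quantification of glycoform relative abundance
    from centroided MS1 data, knockout-based enzyme-specificity calls, and
    position-frequency/sequence-logo summaries. Includes a synthetic LC-MS run
    simulator with known ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    mzR,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
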