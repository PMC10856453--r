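Package: pfasnta
Title: Non-Targeted PFAS Screening and Tissue Differential Analysis for
    LC-HRMS Feature Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-targeted screening of per- and polyfluoroalkyl
    substances (PFAS) in aligned LC-HRMS feature tables: molecular-formula
    chemistry (monoisotopic masses, deprotonated adduct m/z, ppm errors,
    CF2-based Kendrick mass defects), a feature-prioritization cascade
    (procedural-blank subtraction, intensity threshold, Kendrick mass-defect
    window, MS2 availability), suspect-list annotation with CF2 homologous
    series detection, diagnostic-fragment and spectral scoring, and
    Schymanski-style confidence levels, plus liver-versus-muscle differential
    statistics (Welch tests, volcano classification, PCA, hierarchical
    clustering). Ships a curated 60-compound PFAS identification table from a
    roe deer biomonitoring study as a validation fixture, and a synthetic
    LC-HRMS scenario generator that emulates the study design for end-to-end
    planted-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
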