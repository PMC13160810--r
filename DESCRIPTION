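Package: needsmcda
Title: Kano-AHP-TRIZ-TOPSIS Needs Prioritization for Survey-Based Design Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrated multi-criteria pipeline for survey-derived
    requirement prioritization: Kano classification of paired
    functional/dysfunctional questionnaire answers with Better-Worse
    coefficients, questionnaire reliability and validity checks
    (Cronbach's alpha, KMO, Bartlett's sphericity), analytic hierarchy
    process weighting with consistency diagnostics, contradiction-matrix
    lookup of inventive principles, and TOPSIS ranking of design
    alternatives by relative closeness to the ideal solution. Includes
    synthetic-data generators with planted ground truth for
    parameter-recovery testing and a bundled worked example from a needs
    assessment of age-friendly community health emergency stations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
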