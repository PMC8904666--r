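Package: burnoutlink
Title: Crosswalks Between Physician Burnout Measures via IRT and Equipercentile Linking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places ordinal burnout scales on a common reporting metric by
    fixed-parameter graded-response-model calibration and by equipercentile
    equating. Provides marginal maximum likelihood calibration with anchored
    item parameters, summed-score EAP conversion tables, raw-score to t-score
    to anchor-raw-score crosswalks, closest cut-point equivalencies, k-fold
    cross-validated linking accuracy, conditional reliability curves, a
    polychoric-eigenvalue unidimensionality screen, and a synthetic-response
    generator for end-to-end testing of the linking pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
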