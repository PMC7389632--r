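Package: pedpbpk
Title: Whole-Body PBPK Modelling of Lisinopril and Pediatric Dose Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a whole-body physiologically based pharmacokinetic (PBPK)
    model of lisinopril for intravenous and oral (fasting and fed) dosing in
    adults, calibrates it in stages against published reference
    pharmacokinetic values (steady-state volume of distribution, IV exposure,
    oral peak and area under the curve, food-effect shift, multiple-dose
    troughs), scales the calibrated model to virtual pediatric populations
    with age-dependent anthropometry, organ composition and glomerular
    filtration maturation, and searches a graded decremental dose grid for
    doses whose pediatric exposure falls inside the adult reference window.
    The four conventional pediatric dose formulas (Young's rule, Clark's
    rule, weight-based and body-surface-area-based scaling) are included for
    comparison, along with non-compartmental analysis utilities and a
    synthetic-data generator for calibration round-trip testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
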