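Package: renalclock
Title: Sex-Specific Circadian Simulation of Rat Kidney Sodium Transport and
    Oxygenation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduced-order steady-state simulator of sex-specific and
    circadian-regulated sodium handling in the rat kidney. Sinusoidal
    circadian drivers modulate the glomerular filtration rate and the
    apical sodium transporters (NHE3, SGLT1, NKCC2, NCC, ENaC) of a
    ten-segment nephron chain; active transport is converted to oxygen
    consumption through the Na-K-ATPase stoichiometry (15 Na+ per O2),
    and outer-medullary oxygen tension follows from a delivery, shunt and
    consumption balance. Free transport parameters are calibrated by
    deterministic least squares against published model predictions, and
    loop-diuretic (NKCC2 inhibition) and ENaC-inhibition protocols are
    provided as intervention scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
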