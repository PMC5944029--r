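Package: ecmoflow
Title: Reduced-Order Hemodynamics of Peripheral VA-ECMO Perfusion
Version: 0.1.0
Authors@R:
    person("ecmoflow", "developers", email = "ecmoflow@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis of perfusion level during peripheral
    veno-arterial extracorporeal membrane oxygenation (VA-ECMO). Models the
    aorta-branch-femoral arterial tree as a linear Womersley transmission-line
    network driven by a pulsatile cardiac source and a non-pulsatile femoral
    ECMO return, sweeps the blood assist index (BAI), and computes the
    hemodynamic index suite: BAI, upper/lower flow-split ratios, harmonic
    index of pulsatility, oscillatory shear index, regional wall shear
    stress, and the cardiac/ECMO flow-interface (watershed) location.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
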