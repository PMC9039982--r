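Package: aprvdp
Title: Virtual ARDS Patients and Bedside Driving-Pressure Estimation for
    Airway Pressure Release Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator of the ventilated ARDS lung built from
    100 independently configurable alveolar compartments with threshold
    opening pressures, series dead space and alveolar-capillary gas
    exchange.  Virtual patients are calibrated to bedside targets (blood
    gases, airway pressures, functional residual capacity) with a
    real-coded genetic algorithm, then ventilated under airway pressure
    release ventilation (APRV) or volume-controlled ventilation.  The
    package computes the true ventilator driving pressure from simulated
    lung pressure waveforms and compares it against three bedside
    estimators (mono-exponential decay, expiratory time-constant formulas,
    and a volume-controlled ventilation switch) using Bland-Altman and
    correlation analyses over synthetic patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
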