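Package: cardioclamp
Title: Cellular Electrophysiology Analysis for hiPSC-Derived Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in-vitro cardiac cellular electrophysiology:
    voltage-clamp sodium-current gating analysis (Boltzmann steady-state
    activation/inactivation fits, biexponential inactivation kinetics,
    double-pulse recovery from inactivation and entry into slow inactivation,
    membrane capacitance from capacitive transients, IKr peak/tail currents),
    current-clamp action-potential feature extraction with ventricular-like
    subtype classification and triggered-activity detection, calcium-transient
    parameterization with a five-class abnormality taxonomy, microelectrode-array
    field-potential analysis with Bazett rate correction, and qPCR
    allelic-imbalance standard curves with delta-delta-Ct expression. A
    synthetic-data generator produces ground-truth recordings for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
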