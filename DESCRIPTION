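Package: rotabar
Title: Restricted-Rotation Analysis of Sugar (Thio)urea Derivatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hindered rotation in carbohydrate-derived
    ureas and thioureas: dynamic-NMR two-site exchange lineshape simulation and
    coalescence-based Eyring barrier estimation from variable-temperature
    series; rotamer (Z/E) and atropisomer (M/P) descriptor assignment,
    enumeration, and Boltzmann population weights; periodic torsional-scan
    stationary-point and barrier analysis; Cartesian geometry measurements
    (dihedrals, virtual angles, van der Waals contacts, Cremer-Pople ring
    puckering, Karplus couplings); and molecular-formula arithmetic (elemental
    analysis, monoisotopic and adduct masses, chlorine/sulfur isotope
    patterns).  A synthetic-data generator with declared ground truth stands in
    for quantum-chemistry outputs and spectrometer data, and a small pipeline
    runner ties the stages into reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
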