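Package: pncsense
Title: Acoustic Phononic-Crystal Biosensor Simulation for Breath CO2 Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional acoustic phononic crystal built from a
    main duct loaded with periodic open and closed side-branch resonators and a
    central defect guide, used as a capnographic biosensor for carbon dioxide in
    dry exhaled breath. Implements the acoustic two-port transfer-matrix method
    for the transmittance spectrum, the Bloch dispersion relation (Green surface
    function form) for the band structure and band gaps, effective sound speed
    and density of gas mixtures, adaptive localisation of the high-Q defect
    resonance and its linewidth, the full sensor figure-of-merit suite
    (sensitivity, FoM, quality factor, detection limit, SNR, resolution), linear
    CO2 calibration fits, one-parameter geometry sweeps with optimum selection,
    and a YAML-configured command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
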