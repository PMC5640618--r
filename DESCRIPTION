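Package: tripleoxy
Title: Triple-Oxygen-Isotope Budget of Tropospheric CO2
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting the oxygen-17 anomaly (Delta'17O) of
    tropospheric carbon dioxide. Provides triple-oxygen-isotope algebra in
    the logarithmic and linear conventions, construction of CO2 source
    endmembers from water-CO2 equilibration, a steady-state isoflux box
    model yielding the gross terrestrial cycling flux and the oxygen-isotope
    residence time of atmospheric CO2, inversion of the terrestrial flux for
    gross primary productivity and soil invasion under plant-uptake
    scenarios, analytic and Monte Carlo uncertainty propagation,
    sensitivity scans, station measurement statistics (including
    reduced-major-axis regression), and a synthetic flask-station data
    generator for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
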