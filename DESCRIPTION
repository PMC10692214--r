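Package: lymphchain
Title: One-Dimensional Simulation of Pacemaker-Driven Lymph Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates lymph transport through a chain of contractile
    lymphangions. Contractions are prescribed by a spatiotemporal
    activation field built from bivariate-Gaussian pacemaker signals
    (initiation sites, conduction speed, frequency), the vessel wall
    interpolates between pre- and peak-twitch pressure-diameter curves,
    secondary valves are sigmoidal pressure-dependent resistances, and
    the coupled 1D mass/momentum balance is solved with an implicit
    finite-difference scheme. Ships wild-type and Connexin-45 knock-out
    contractility presets and a metrics suite (ejection fraction,
    fractional pump function, wall shear stress and its signal-to-noise
    ratio, valvular energy loss, activation integration, bottleneck
    tracking).
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
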