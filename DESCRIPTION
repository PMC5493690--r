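Package: odortunnel
Title: Dissipative Inelastic Electron Tunneling Rates for Olfactory Odorant Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rate-calculation toolkit for the dissipative quantum (vibrational)
    model of olfaction. An odorant's contorsional mode is treated as an
    asymmetric double-well two-level system coupled to a donor/acceptor
    electron pair and an Ohmic harmonic bath. The package provides the
    polaron-frame quantities, closed-form high-temperature (Marcus-type)
    elastic and inelastic electron-transfer rates for all odorant transitions,
    a numerical rate oracle built from the bath correlation function, and the
    pressure, isotope and chirality phenomenology layered on the rate engine,
    together with parameter-sweep and tabulation tools and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
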