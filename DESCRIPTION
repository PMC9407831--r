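Package: liqemit
Title: Two-Stage Mechanistic Model of Chemical Emission from Liquid
    Products Applied on Indoor Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the indoor air concentration of a chemical emitted
    by a liquid product (cleaning agent, personal care product) applied on
    a permeable surface or on human skin.  While the liquid layer exists
    (stage 1) the chemical volatilises into room air by convective mass
    transfer and simultaneously diffuses into the substrate; after the
    liquid is depleted (stage 2) the substrate re-emits the absorbed
    chemical into the air.  The coupled substrate-diffusion / room-air
    system is integrated with a conservative cell-centred finite-volume
    scheme with automatic stage switching, a mass-conservation audit, and
    time-step refinement until convergence.  Includes emission metrics
    (peak concentration, time to peak, liquid-to-air and re-emission mass
    fractions), a one-at-a-time parameter sweep engine, packaged
    validation scenarios, a synthetic scenario generator, JSON
    configuration I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
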