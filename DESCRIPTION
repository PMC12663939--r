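Package: oxzhydro
Title: Outside-Xylem Hydraulics and Nonstomatal Control of Transpiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for analysing nonstomatal control of
    transpiration in leaves. Provides psychrometric conversions between water
    potential, equivalent relative humidity and vapor mole fraction; per
    measurement conductance analytics for gas-exchange campaigns paired with
    nanoreporter readings of apoplastic water potential (outside-xylem-zone
    conductance, undersaturation-corrected stomatal conductance, and the
    delta-phenotypes of undersaturation, conductance error and water-use
    efficiency gain); a two-compartment pseudo-one-dimensional steady-state
    model of water flow through the outside-xylem zone with a variable
    plasma-membrane conductance and a scenario engine for competing hydraulic
    architectures; bounded sigmoid membrane-law fitting with parameter
    recovery diagnostics; synthetic measurement campaigns and synthetic FRET
    nanosensor images with known ground truth; and pixel-level FRET-to-water
    potential mapping with histogram modes and cell morphometrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
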