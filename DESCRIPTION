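Package: magnetodose
Title: Dosimetry of Magnetomechanical Nanoparticle Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the mechanical dose delivered by
    superparamagnetic iron oxide nanoparticles (SPIONs) in a gradient
    magnetic field. Converts superparticle geometry and composition into
    per-particle iron mass, elemental-iron measurements into particle
    counts, and magnetization models and gradient-field generators
    (electromagnet calibrations, annular magnet arrays) into per-particle,
    per-cell, and per-tissue forces. Includes exponential clearance
    fitting for nanoparticle biodistribution time series, intermittent
    stimulation-protocol schedules with cumulative mechanical impulse,
    standard nerve-regeneration bioassay metrics (sciatic functional
    index, CCK-8 viability, orientation index, G-ratio, calcium-trace
    dF/F0, motor nerve conduction velocity, F/G-actin ratio), and
    synthetic-data generators that emulate the statistical structure of
    the corresponding measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
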