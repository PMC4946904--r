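Package: phloemflow
Title: Sieve-Tube Hydraulics and Pressure-Flow Feasibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of phloem transport under the Muench
    pressure-flow hypothesis: sieve-tube specific conductivity from measured
    sieve-element and sieve-plate pore geometry (serial lumen plus plate
    resistance with Sampson-corrected pores), Hagen-Poiseuille flow
    arithmetic relating velocity, pressure differential, tube length,
    viscosity and conductivity, fluorescence-lifetime (molecular rotor)
    viscometry with an aqueous-sucrose viscosity correlation, radiotracer
    transit-time velocimetry, and a source-sink pressure feasibility report.
    Includes a seeded synthetic-data generator for all input tables and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
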