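Package: spo11dock
Title: Rigid-Body Docking and Interface Geometry of DNA-End-Bound Protein
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural-modelling toolkit for analysing how DNA-end-binding
    protein complexes such as the meiotic Spo11 core complex arrange on
    duplex DNA.  Builds idealized B-form DNA rails with per-base-pair rigid
    frames, docks two copies of a DNA-bound complex on opposite ends of a
    duplex and scans steric clashes against duplex length to find the
    shortest co-oriented clash-free spacing, constructs topoisomerase
    VI-templated pre-break dimer models by domain-split rigid-body
    alignment, and computes the supporting interface metrics: Kabsch
    superposition RMSDs, helical-axis angles and offsets, van der Waals
    clash reports, protein-DNA contact maps, and Shrake-Rupley buried
    interface areas.  Includes a synthetic-fixture generator with
    analytically known clash-onset geometry so the full pipeline is testable
    without downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
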