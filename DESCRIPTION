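Package: sonasim
Title: Simulated Control Stack for MR-Guided Focused Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free control stack for magnetic resonance guided
    high-intensity focused ultrasound (MR-HIFU) research. Provides an
    immutable treatment-protocol model with JSON serialization, a
    deterministic protocol-execution engine with real-time modification and
    status querying (in-process or over TCP), a 256-element phased-array
    acoustic field simulator (Rayleigh integral, electronic steering,
    virtual hydrophone), a Pennes bioheat solver, a virtual MR scanner
    producing dynamic magnitude/phase and two-echo image streams with
    queue semantics, and MR thermometry (proton-resonance-frequency-shift
    phase mapping with drift correction, and two-echo T2 mapping for
    fatty tissue). End-to-end applications reproduce desk-scale heating
    patterns, per-element transducer scans, and small-animal thermometry
    loops entirely in simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
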