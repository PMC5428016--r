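Package: mstdesign
Title: Design Rules and Physical Models for Microfluidic Sample Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and numerical models for designing microfluidic
    sample traps (MSTs), the wells and recesses used to capture and culture
    single cells, spheroids and submillimetre tissue samples next to a
    perfusable channel. Implements wall-corrected Stokes sedimentation for
    confined settling, the critical flow-rate operating window bounded by
    tissue ejection (lift) and damaging shear stress, the anoxia-limited
    maximum tissue diameter, Michaelis-Menten diffusion-reaction depletion
    of finite nutrients solved on a conservative sphere-in-shell finite
    volume grid, the linear medium-replenishment law fitted to depletion
    sweeps, and Damkohler-number channel-length limits. A design advisor
    turns these models into concrete trap dimensions, medium volumes and
    replenishment schedules, and evaluates published trap designs against
    the model. A small command-line interface regenerates every summary
    table from a shell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
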