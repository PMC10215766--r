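Package: delamsim
Title: Diffusion-Based Delamination Models for Metal-Polymer Implant
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Solvers and estimation tools for fluid-driven failure of
    silicone-encapsulated metal components in active implantable medical
    devices such as cochlear implants.  Implements one-dimensional Fickian
    volume diffusion through a silicone slab with a colour-change
    breakthrough criterion, Stefan-type moving-boundary diffusion along the
    metal-polymer interface (exact similarity solution,
    heat-balance-integral approximation, and a front-tracking
    finite-difference solver), a kinematic ramp-release model of mechanical
    delamination, a corrosion-threshold interlayer transport model,
    Einstein-Smoluchowski diffusion-coefficient estimation,
    square-root-of-time front-law fitting, and synthetic experiment
    generators for both assay types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
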