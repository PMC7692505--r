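Package: hemopore
Title: Pore Structure and Protein Fouling Analysis for Hemoconcentration Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the pore structure of hollow-fibre
    hemoconcentration (ultrafiltration) membranes before and after blood
    contact. Implements the tortuous pore diffusion (TPD) model linking pure
    water permeability to an equivalent cylindrical pore radius via
    Hagen-Poiseuille flow with a tortuosity correction, hindered-transport
    solute permeability with steric and wall-friction factors, dead-end
    filtration (STOP method) permeability arithmetic, and a scanning probe
    microscopy (SPM) topography pipeline: plane flattening, height-threshold
    pore segmentation, Feret-diameter line analysis, equivalent-area
    diameters and pore-size distributions. A seeded synthetic topography
    generator emulates rough polymer surfaces with elliptical nanopores and a
    protein-adsorption fouling transform, so the whole measurement pipeline
    can be validated by parameter recovery. A fouling comparison stage
    combines permeability retention, per-condition TPD diameters, paired
    t-tests and albumin sieving coefficients into a single report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
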