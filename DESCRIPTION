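Package: fibrogrid
Title: Spatially Resolved Simulation of Cardiac Fibroblast Signaling and
    Extracellular Matrix Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reaction-diffusion simulator of cardiac scar tissue. Every
    cell of an N x N grid runs the same ordinary-differential-equation
    model of the cardiac fibroblast signaling network (inputs, receptors,
    second messengers, kinases, MAPK cascades, transcription factors,
    mechanotransduction, and extracellular-matrix outputs); cells are
    coupled by four diffusible paracrine feedback molecules and by slowly
    diffusing extracellular-matrix fields on a periodic lattice. Includes
    a curated reference network of 132 species, brush-mask spatial
    stimulation, scenario presets, clamped forward-Euler integration with
    adaptive stepping, region summary statistics, heatmap rendering, and a
    command-line interface with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
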