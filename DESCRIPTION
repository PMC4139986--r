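Package: nodusim
Title: Cell-Based Simulation of Carrier-Mediated Auxin Transport in
    Actinorhizal Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual-tissue modeling of auxin fluxes in actinorhizal root
    nodules. Digitizes segmented nodule-section label maps into cell-adjacency
    graphs, generates synthetic nodule tissues with an apical meristem and
    hypertrophied Frankia-infected cortical cells, places AUX1-like influx and
    PIN1-like efflux carriers on membranes according to cell-type rules,
    integrates linear carrier-mediated transport dynamics to steady state
    (with an independent direct linear solve), classifies the resulting
    accumulation pattern by cell type, and sweeps the parameter space of the
    transport model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    grDevices,
    stats,
    utils
Suggests:
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
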