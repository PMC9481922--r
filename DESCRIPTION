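Package: mosassay
Title: Analytics for Micro-Organosphere Drug Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analytics for micro-organosphere (MOS) plate-based
    drug assays: instance segmentation of organospheres from whole-well
    bright-field images, per-object size and integrated live/dead (calcein-AM
    / ethidium homodimer) fluorescence readouts, day-0 total-surface-area
    normalization of bulk CellTiter-Glo viability signals, dose-response and
    AUC computation, cytostatic-versus-cytotoxic effect calling, and
    resistant-clone detection. Includes a fully seeded synthetic MOS plate
    simulator (Poisson droplet encapsulation, spheroid growth under Hill-type
    drug-effect models, three-channel image rendering with ground-truth
    masks, and luminescence simulation) so that every stage of the pipeline
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
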