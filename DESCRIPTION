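Package: dianascreen
Title: Analysis and Simulation of DNA-Linked Inhibitor Antibody Assay
    (DIANA) Screens
Version: 0.1.0
Authors@R:
    person("DIANA", "Screen Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for competitive-binding high-throughput screens read out
    by quantitative PCR (the DNA-linked Inhibitor Antibody Assay, DIANA),
    developed around a PD-L1 ligand-discovery workflow.  Provides the
    three-species competitive binding equilibrium forward model and its
    mapping to qPCR quantification cycles (Cq), single-well dissociation
    constant (Kd) estimation from delta-Cq, probe Kd calibration from
    titrations, plate quality control (assay window, Z'-factor), delta-Cq
    hit calling with configurable thresholds, counter-screen interference
    filtering, pooled-library deconvolution planning and confirmation,
    screen summary statistics, a synthetic screen generator with planted
    binders and assay interferers, and a file-based pipeline with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
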