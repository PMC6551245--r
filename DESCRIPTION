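Package: modescape
Title: Sample-Based Reconstruction of Protein Energy Landscapes from
    Collective-Motion Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic exploration of protein conformational space in a
    low-dimensional space of collective variables.  Variable bases are
    interchangeable: principal components extracted from an ensemble of
    CA traces, or normal modes of an anisotropic elastic network model
    built from a single structure.  The package provides CA-trace
    geometry (Kabsch superposition, least RMSD), basis extraction and
    comparison, mode-count reconstruction-loss analysis, eigenvalue- and
    frequency-scaled global motion vectors, a grid-weighted
    selection/variation exploration loop with a coarse-grained CA energy
    surrogate and chain regularizer, deformation series along single
    axes, and energy-landscape projection tables.  A synthetic two-basin
    hinge-motion fixture generator supports fully reproducible
    experiments without external structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
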