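Package: radialsim
Title: Radial-Shell Protein Similarity and Signed-Network Pathway Ranking
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Alignment-free comparison of protein structures by radial-shell
    atomic density and composition. Computes nine per-parameter similarities
    for an ordered protein pair (shell-density profile, atom count, residue
    count, residue-type count, C/N/O proportions, and P/S radial position),
    combines them by a trained weighted sum, fits the nine weights from
    labelled pairs by full-batch gradient descent, and propagates the
    resulting similarity scores as source priors through a signed regulatory
    network (noisy-OR with inhibitor gating) to rank candidate root-to-sink
    regulatory pathways. Includes generators for synthetic structures,
    training tables, and signed networks with a planted dominant pathway.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
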