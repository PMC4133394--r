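Package: pcndiff
Title: Differential Analysis of Protein Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds coarse-grained protein contact networks (PCNs) from
    C-alpha coordinates of crystal structures, computes residue-level
    network metrics (degree, clustering coefficient, betweenness and
    closeness centrality, shortest paths) and fast-greedy modularity
    communities, and quantifies the contacts made and lost between a
    reference structure and a series of mutants, classifying each contact
    change by sequence range, secondary-structure context, proximity to
    the active site and the chain termini.  Includes least-squares
    (Kabsch) superposition for cross-structure and residue-wise RMSD,
    a synthetic single-chain backbone generator with ground-truth contact
    edits for validation, and ring-graph layouts of differential contact
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
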