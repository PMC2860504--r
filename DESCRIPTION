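Package: ecmap
Title: Eigenvector Centrality Mapping for Functional Imaging Time Series
Version: 0.1.0
Authors@R: person("ECM", "Maintainers", email = "ecmap@example.org", role = c("aut", "cre"))
Description: Voxel-wise network centrality mapping for 4D functional imaging
    data. Computes eigenvector, degree and betweenness centrality over
    voxel-pair similarity matrices built from scaled linear correlation or
    lag-window spectral coherence, using matrix-free power iteration so that
    whole-mask similarity matrices never need to be materialized. Includes a
    minimal NIfTI-1 reader/writer, a group-level statistical layer (rank-based
    Gaussianization, paired t-maps, Monte-Carlo cluster-size/cluster-value
    multiple-comparison correction), a synthetic generator of masked BOLD-like
    data with planted hub/module structure, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
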