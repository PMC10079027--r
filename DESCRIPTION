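Package: brainhub
Title: Structural Connectome Construction, Hub Centrality, and Global Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds weighted structural connectomes from streamline endpoint
    records and a parcellation label volume, averages them over runs and
    subjects, and contrasts an extended (brainstem-inclusive) node set against
    a restricted Desikan-Killiany-style node set, with optional volume
    normalization of edge weights. Provides degree, eigenvector, and
    betweenness centrality with cross-subject ranking tables, and global
    topology measures (global efficiency, modularity maximized by a Louvain
    heuristic, and global reaching centrality). Includes a synthetic
    multi-subject endpoint generator with planted hubs and community structure
    so the full pipeline runs and is testable without diffusion MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
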