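Package: hypoparc
Title: Consensus Community Detection Parcellation of Hypothalamic
    Resting-State Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for data-driven functional parcellation of
    the human hypothalamus from voxel-wise resting-state functional
    connectivity. Implements Louvain modularity optimisation with a
    100-iteration consensus (co-assignment) procedure, kneedle knee-point
    detection for run-level exclusion of high-variance voxels and for
    selecting the number of cortical clusters via the Calinski-Harabasz
    index, Fisher-z connectivity matrices under per-run voxel availability,
    and a 2 (cortical network) x 4 (hypothalamic community)
    repeated-measures ANOVA with Greenhouse-Geisser correction and LSD
    post-hoc tests. A multi-subject synthetic-data generator with planted
    block-covariance community structure, planted cortical coupling
    profiles, artifact voxels and missing runs makes every stage testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    car,
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
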