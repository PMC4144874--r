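Package: tractnet
Title: Weighted White-Matter Connectome Backbones and Small-World Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted structural brain networks from directed
    streamline-count matrices produced by probabilistic tractography,
    screens scans for excessive head motion, extracts maximum-spanning-tree
    connectivity backbones at a target average degree, computes weighted
    nodal and global graph metrics (strength, generalized clustering,
    harmonic-mean characteristic path length, betweenness centrality,
    global and local efficiency), assesses small-world organization
    against degree-preserving rewired null ensembles, and compares two
    groups of subjects with nodal and global two-sample tests. Includes a
    synthetic cohort generator with known injected group effects so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
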