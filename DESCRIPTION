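Package: aogm
Title: Cell Tracking Accuracy from Acyclic Oriented Graph Matching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Benchmarking of cell tracking algorithms against a ground-truth
    reference. Cell lineages are represented as acyclic oriented graphs whose
    vertices are spatially extended markers (labelled pixel or voxel sets) and
    whose edges carry track-link or parent-link semantics. A strict
    majority-overlap detection test pairs reference and computed markers
    uniquely, the six tracking error types (missed splits, false negative and
    false positive detections, redundant, missing and wrongly labelled links)
    are counted, and aggregated into a single weighted graph-transformation
    cost with detection-only and association-only variants. Includes readers
    and writers for label-mask TIFF directories in the Cell Tracking Challenge
    layout and a JSON fixture dialect, a weight-sensitivity analysis of
    algorithm rankings over 2-D weight-space sectors, a seeded synthetic
    lineage generator with an error injector producing known expected error
    counts, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tiff,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
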