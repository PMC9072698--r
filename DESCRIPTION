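Package: centerpick
Title: Continual-Learning Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exemplar-based continual-learning particle picker for cryo-EM
    micrographs. Implements an anchor-free keypoint (center-heatmap) detector
    with offset and optional size regression, three training modes (joint,
    fine-tune, and continual learning with exemplar rehearsal, knowledge
    distillation and parameter regularization), sparse-annotation focal loss
    with pseudo-labels, standard AP/AR detection evaluation with dataset
    complexity and forgetting-rate scores, a curvature-constrained line
    tracing algorithm for fiber picking, and a synthetic micrograph generator
    with exact ground truth for benchmarking. Reads and writes MRC, PNG and
    TIFF micrographs and TSV, EMAN BOX and RELION STAR coordinate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
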