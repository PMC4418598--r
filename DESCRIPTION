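Package: pairnet
Title: Paired RNA-Seq Differential Expression and Coexpression Network
    Rewiring Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired (before/after) bulk RNA-seq
    studies. Implements per-gene negative-binomial mixed-model
    differential expression with subject random intercepts and
    size-factor offsets, weighted gene-coexpression network construction
    (soft-thresholded adjacency, topological overlap, tree-based dynamic
    cut, module merging, eigengenes, module membership, hubgenes),
    jackknife module-stability assessment with Jaccard matching,
    eigengene-trait association, and cross-condition module-preservation
    ("disconnection") analysis. Includes a synthetic-data generator that
    plants differential expression, coexpression modules and rewired
    genes in paired negative-binomial counts, and clinical phenotype
    utilities (HOMA-IR, metabolic-syndrome and diabetes classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
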