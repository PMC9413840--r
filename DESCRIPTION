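Package: mstconnect
Title: Minimum-Spanning-Tree Connectome Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a resting-state fMRI
    analysis pipeline for studying treatment response in PTSD: head-motion
    quantification (Jenkinson framewise displacement, spike censoring),
    36-parameter nuisance regression, amplitude of low-frequency
    fluctuations (ALFF), minimum-spanning-tree (MST) connectome metrics at
    the global and nodal level, and a permutation/FDR inferential layer
    including motion-sensitivity analyses. A synthetic multi-subject cohort
    generator with planted tree-structured connectivity and clinical
    response effects allows the full pipeline to run end-to-end without
    real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
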