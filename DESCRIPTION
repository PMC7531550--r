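Package: episodeRSA
Title: Design, Simulation and Representational Similarity Analysis of
    Multistep fMRI Task Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for event-related fMRI experiments in which participants
    execute memorized multistep task episodes. Generates transition-balanced,
    efficiency-optimized run designs; simulates BOLD data with a planted
    representational geometry (room, task, step-position, item and display
    components) together with behavioural responses; fits finite impulse
    response and onset/epoch/offset general linear models; computes
    cross-validated linear discriminant contrast (LDC) dissimilarities with
    multivariate noise normalization; decomposes representational
    dissimilarity matrices into room, task, step and item components with a
    visual-difference confound regressor and a cross-validated reaction-time
    covariate; and provides searchlight mapping plus the group-level
    inferential layer (one-sample and paired tests, repeated-measures ANOVA
    with polynomial trends and Greenhouse-Geisser correction, FDR control).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
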