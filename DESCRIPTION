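Package: rsacodes
Title: Representational Similarity Analysis of Visual and Conceptual Object Codes
Version: 0.1.0
Authors@R: person("rsacodes", "maintainers", email = "rsacodes@example.org", role = c("aut", "cre"))
Description: An end-to-end representational similarity analysis (RSA) pipeline for
    studying how visual and conceptual object features are coded across brain
    regions. Builds behavior-based representational dissimilarity matrices (RDMs)
    from pairwise similarity ratings, semantic feature-generation norms, and word
    embedding vectors; estimates object-specific multi-voxel t-patterns by GLM from
    event-related time series; computes first-level correlation-distance RDMs and
    within-object cross-context similarity; performs second-level RSA inference
    (tie-aware Kendall tau-a, stimulus-label randomization tests, one-sided Wilcoxon
    signed-rank tests, Bonferroni correction, repeated-measures interaction tests);
    maps model fit over the volume with k-nearest-voxel searchlights; and carries
    out group inference with threshold-free cluster enhancement (TFCE) and
    max-statistic permutation familywise-error control, plus cluster reporting and
    voxel-overlap analysis. A synthetic-data module generates every input with
    known representational structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
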