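Package: neurodims
Title: Neurosemantic Dimensions of Abstract Concepts from fMRI Activation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multivariate pattern analysis of concept-evoked fMRI activation:
    stability-based voxel selection, Gaussian naive Bayes decoding scored by
    normalized rank accuracy under within-participant, between-participant and
    cross-language cross-validation schemes, a two-level (participant then
    group) principal-axis factor analysis that extracts shared semantic
    dimensions and localizes them as contiguous voxel clusters, and
    leave-one-concept-out prediction of activation patterns from behavioral
    ratings. Includes a synthetic two-cohort activation generator with planted
    latent dimensions so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
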