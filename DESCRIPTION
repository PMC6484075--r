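Package: disturbnet
Title: Abundance-Pattern Classification and Lotka-Volterra Network
    Inference for Disturbed Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the systems-level analysis of a microbial community
    observed through a press disturbance. Classifies taxa from a relative
    abundance time series by abundance level (high/low/rare), temporal
    presence (core/non-core), before-vs-after abundance stability
    (F test of variances plus coefficient-of-variation comparison) and
    disturbance response (induced/repressed); computes community summary
    statistics (Shannon diversity, richness, archaeal fraction, PCA,
    variance-aware two-phase tests); infers signed, directed interaction
    networks with a discrete-time generalized Lotka-Volterra ridge
    regression wrapped in a member-subsampling ensemble with
    sign-consensus and strength filtering; and compares pre- and
    post-disturbance networks by in-degree and betweenness centrality.
    Includes a fully seeded synthetic-data generator (generalized
    Lotka-Volterra dynamics with a disturbance window, observation noise
    and compositional closure) providing ground truth for end-to-end
    validation, plus a one-call pipeline with reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
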