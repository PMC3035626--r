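Package: spikescales
Title: Multi-Timescale Analysis of Multineuronal Spike Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies stereotypical multineuronal activity
    patterns across timescales ranging from spike synchrony to mean firing
    rate. Spike trains are low-pass filtered with causal exponential kernels,
    sampled into population activity vectors, and clustered with a
    three-dimensional Kohonen self-organizing map (or K-means) into model
    vectors ("patterns"). The package quantifies pattern-to-stimulus
    specificity, decodes stimulus identity with mean-rate, specificity and
    trajectory classifiers under repeated half-split cross-validation,
    resolves discriminative information in time via Cohen's d effect-size
    timecourses, and provides spike-time jitter, window-shuffle and
    burst-removal controls. A seeded inhomogeneous-Poisson generator
    emulates slow (grating-like), fast (flashed-sequence) and mixed
    (movie-like) stimulus regimes for validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
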