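Package: crossfeed
Title: Batch Co-Culture Cross-Feeding Dynamics and Variance-Based
    Global Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic batch-culture models of syntrophic
    (cross-feeding) microbial communities built from auxotrophic strains
    that exchange overproduced metabolites, with Monod uptake kinetics,
    configurable leak fractions, metabolite toxicity and a
    division-of-labour heterologous-pathway extension. Provides a stiff
    ODE batch simulator with batch-completion detection and performance
    metrics (final population, batch time, composition, growth and
    exchange fluxes, productivity, yield), an extended Fourier amplitude
    sensitivity test (eFAST) with search-curve resampling and
    dummy-parameter significance testing, named community scenario
    presets with experimental dials (promoter strength, inoculum ratio,
    supplementation, density), a synthetic plate-reader data generator
    with subpopulation unmixing and growth-parameter recovery, and
    command-line entry points for reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
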