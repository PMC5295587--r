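Package: defscreen
Title: Deficiency-Screen Mapping of Temperature-Dependent Hybrid
    Incompatibilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for Drosophila-style deficiency screens that
    map recessive hybrid-incompatibility alleles at two rearing
    temperatures.  Provides per-deficiency relative-viability inference
    with a one-degree-of-freedom chi-square segregation test, minimal
    causal-region counting over overlapping deletions (minimum interval
    stabbing), randomization tests for the overlap of incompatibility
    sets between conditions with a hypergeometric oracle, paired t-tests
    and factorial linear models of temperature-by-species-by-chromosome
    effects with simultaneous (max-t) contrasts, and a seeded synthetic
    cross simulator that emulates balancer-versus-deficiency progeny
    counts with temperature-specific penetrance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    IRanges,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
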