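Package: pulsecr
Title: Stage-Structured Consumer-Resource Dynamics with Pulsed Seasonal
    Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a semi-discrete stage-structured consumer-resource
    biomass model in which adult consumers reproduce in a single pulse at
    the start of each growing season.  Provides the within-season biomass
    dynamics (semi-chemostat resource, juvenile and adult consumer stages,
    reproductive energy storage, starvation switching and a
    resource-dependent maturation rate), the season map obtained by
    composing one season of continuous dynamics with the discrete
    reproduction pulse, fixed points of that map with stability
    classification, bifurcation sweeps over consumer background mortality,
    persistence and invasion boundaries with bistability (Allee effect)
    detection, and within-season life-history analysis of the expected
    end-of-season reproductive output as a function of maturation timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    pracma
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
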