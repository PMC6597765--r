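Package: coidom
Title: Co-Infection Dominance and Evolutionary Emergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how two-strain co-infections shape pathogen
    evolution. A within-host ordinary-differential-equation model of a
    wild-type and a mutant strain under a shared immune response yields total
    transmission, bottleneck-dependent co-transmission probabilities and the
    dominance of the mutant; a three-type branching process converts these
    quantities into probabilities of evolutionary emergence via probability
    generating functions, with a Monte-Carlo chain simulator as an independent
    check. Includes Latin hypercube sampling and partial rank correlation
    (PRCC) machinery with bootstrap confidence intervals for global
    sensitivity analysis, and a pipeline linking within-host phenotypes to
    emergence probabilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
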