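Package: krillmse
Title: Spatial Krill-Predator-Fishery Simulation and Management Strategy
    Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spatially resolved, seasonal delay-difference simulator of the
    Antarctic krill fishery and its dependent predators (penguins, seals,
    whales, fish) across small-scale management units, with a management
    strategy evaluation layer. Compares feedback catch-allocation rules driven
    by krill density or by changes in breeding-penguin abundance against a
    no-take marine protected area, under a climate-driven decline in mean
    individual krill mass. Paired Monte-Carlo ensembles over a reference set
    of parameterizations yield counterfactual scenario-to-base-case ratios of
    predator abundance, catch, and the probability that fishing is suspended
    because krill density falls below a threshold.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
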