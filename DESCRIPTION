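Package: siuptake
Title: Actor Networks and Bayesian Belief Modelling of Sustainable-Intensification Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how groups of actors (local/external, market/government,
    formal/informal) enable or block farmers' uptake of sustainable-intensification
    measures in a peri-urban landscape. Provides a synthetic farm-population
    generator emulating the case-study structure (quota or Bernoulli sampling,
    Jenks natural-breaks location classes, payment-derived farm sizes, synthetic
    accounting tables), weighted influence-network indicators (in/outdegree,
    betweenness), a discrete Bayesian belief network engine with exact inference
    by variable elimination, rank-based conditional-probability elicitation
    calibrated to printed baseline marginals, a scenario sensitivity suite with
    trade-off/synergy classification, and a quantile-threshold efficiency
    adoption score.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
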