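Package: cryptdrift
Title: Mutation Accumulation, Aging, and Tumorigenesis Risk in Intestinal
    Stem-Cell Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic models of somatic evolution in
    intestinal crypt systems. Implements a compartmental model of the crypt
    (stem-cell niche, displaced stem cells, transit-amplifying pools, and the
    postmitotic epithelium), Moran-ring fixation probabilities for mutant
    stem-cell lineages, a mirrored-exponential distribution of fitness
    effects, and the recursion describing successive fixed mutations in a
    niche. These pieces are combined into organism-scale predictions: the
    expected attrition of the postmitotic epithelium over a lifetime
    (Muller's ratchet in somatic tissue) and the probability that mutation
    accumulation initiates tumorigenesis, scanned across stem-cell niche
    sizes at constant total tissue output to expose the trade-off between
    aging and tumour risk. Exact Gillespie simulators of the crypt and of
    ring-Moran fixation dynamics are included as independent stochastic
    checks of the analytic pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
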