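Package: thermetab
Title: Thermal Metabolic Phenotyping from Intermittent-Flow Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement-to-inference chain for thermal metabolic phenotyping
    of small fish. Converts raw intermittent-flow respirometry oxygen traces
    into standard, routine and maximum metabolic rates (SMR, RMR, MMR) with
    background (blank) correction and lowest-decile SMR estimation; estimates
    allometric scaling exponents and Arrhenius activation energies of
    mass-normalized metabolic rates; and fits the downstream inference layer:
    candidate linear mixed models ranked and averaged by AICc, a binomial
    mixed model for boldness, a Poisson-lognormal mixed model for activity,
    and right-censored (Tobit) regressions of emergence latency on metabolic
    rate. A synthetic-data generator emulates the full study design (flush/
    wait/measure cycles, drifting microbial blanks, activity bursts, and a
    cohort with thermal-history by acclimation-temperature structure) so that
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    rlang,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    ggplot2,
    optparse
Config/testthat/edition: 3
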