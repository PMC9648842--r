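Package: comonod
Title: Cybernetic Monod Kinetics for Microbial Co-Culture Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of multi-species microbial co-cultures in batch,
    chemostat and glucose-pulsed continuous bioreactors using Monod-type
    kinetics with cybernetic resource allocation. Each organism carries a set
    of substrate-assimilation pathways gated by virtual key enzymes whose
    synthesis and activity are regulated by matching-law weights against a
    growth-rate objective, reproducing diauxic shifts between glucose and
    overflow metabolites (acetate, ethanol). Includes square-wave dilution
    pulsing, a coexistence scan over dilution rate, pulse frequency and duty
    cycle, a synthetic mini-bioreactor batch-data generator, and bounded
    least-squares estimation of Monod and yield parameters from batch
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
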