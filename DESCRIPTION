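Package: deerseed
Title: Simulation and Inference for Long-Distance Seed Dispersal by Red Deer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mechanistic pipeline for quantifying endozoochorous
    long-distance seed dispersal (LDD) by GPS-collared red deer. Per-seed
    dispersal distances are simulated as the displacement between a random
    deposition endpoint on an individual's movement trajectory and the
    trajectory position one gut-passage time earlier (d = v * p), with
    passage times drawn from an interval-probability retention model. Dung
    seed loads (seedlings per gram dry mass) are computed with control-tray
    contamination filtering, and the inference layer provides variance
    partitioning of LDD probability across individuals and months,
    load-versus-LDD regressions, species-specific seed-load-weighted
    LDD potential with a permutation null model, and a binomial
    across-species meta-test. A synthetic-data generator with a correlated
    random walk over smooth terrain stands in for confidential telemetry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
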