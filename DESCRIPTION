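Package: btexrisk
Title: Probabilistic Health-Risk Assessment for BTEX Inhalation Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic and probabilistic human health-risk assessment for
    inhalation exposure to benzene, toluene, ethylbenzene and xylenes (BTEX)
    in communities near industrial emission sources. Implements hazard
    quotients against inhalation reference concentrations and urinary
    biological exposure indices, chronic daily intake and lifetime cancer
    risk, Monte Carlo uncertainty propagation with parameter sensitivity,
    base-10 log-normal exposure modelling with quantile-based Gaussian
    fitting and Kolmogorov-Smirnov checks, creatinine correction of urinary
    biomarkers, toluene/benzene ratio and ternary-composition source
    apportionment, and a seedable synthetic-data generator reproducing the
    study design the methods assume.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
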