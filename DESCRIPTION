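Package: medflysit
Title: Individual-Based Simulation of Sterile-Male Release Programs in the
    Mediterranean Fruit Fly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A weekly-time-step, individual-based simulator of Mediterranean
    fruit fly (Ceratitis capitata) population dynamics under sterile-male
    release programs. Implements overlapping generations with age-structured
    survival schedules, fitness-weighted mating with polyandry and first-male
    sperm precedence, Poisson fecundity, and Beverton-Holt density-dependent
    larval survival. Compares release systems (radiation-sterilised SIT and
    CRISPR-based sex-conversion/pgSIT strains) by female-population
    trajectories, time to elimination, and the effects of release ratio and
    release interval, with calibration to a stationary pre-release population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
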