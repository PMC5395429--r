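Package: seascaper
Title: Seascape Genetics of Sea Urchin Larval Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seascape-genetics toolkit joining a biophysical Lagrangian
    simulator of sea urchin (Paracentrotus lividus) larval dispersal with a
    population-genomics analysis stage. The dispersal side advects larvae at
    fixed depth through gridded daily ocean velocity and temperature fields
    with fourth-order Runge-Kutta integration, a temperature-gated spawning
    calendar, temperature-triggered mortality, and 5-km arrival buffers, and
    summarises the resulting fluxes as connectivity effectiveness and
    persistence matrices with modified Mann-Kendall interannual trend tests.
    The genetics side provides RAD-SNP filtering rules, diversity statistics,
    Weir-Cockerham F(ST) with permutation and bootstrap inference,
    hierarchical AMOVA with exhaustive partition search, forward-time
    Wright-Fisher drift/migration simulation, and POWSIM-style power
    analysis. Synthetic ocean-field and genotype generators make the full
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
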