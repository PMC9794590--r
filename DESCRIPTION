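Package: schaftosim
Title: Whole-Body PBPK Modelling of Schaftoside After Oral Total Flavonoids
    of Desmodium styracifolium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) simulation of the
    flavone C-glycoside schaftoside after intravenous dosing in rat and oral
    multiple-dose administration of total flavonoids of Desmodium
    styracifolium (TFDS) capsules in human. Provides reference rat and human
    physiologies with chronic-kidney-disease stage scaling and virtual
    population sampling, a perfusion-limited whole-body compartmental ODE
    engine with Weibull dissolution and gastrointestinal transit,
    non-compartmental analysis, fold-error model-qualification statistics,
    local parameter sensitivity analysis, and population comparison
    summaries. Results are returned as tibbles with broom-style tidy()
    and glance() methods and ggplot2 autoplot() graphics.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
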