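Package: pmrft
Title: Theoretical Postmortem Redistribution Factor Modeling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting postmortem drug concentrations with the
    theoretical postmortem redistribution factor (Ft), a closed-form function
    of a drug's characteristic liver-to-peripheral-blood (L/P) ratio. Ships a
    curated 44-drug reference table of median L/P ratios and published Ft
    values and a 13-record paired antemortem/postmortem case table; estimates
    antemortem whole-blood concentrations from postmortem peripheral blood;
    classifies drugs by redistribution propensity; reproduces the model's
    published validation (per-case factor comparison, ordinary least squares
    regression of theoretical on determined factors, postmortem-delay
    summary); and simulates synthetic paired-case cohorts with multiplicative
    lognormal noise for parameter-recovery experiments. Includes a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
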