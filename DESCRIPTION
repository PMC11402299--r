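Package: avoidmort
Title: Avoidable Mortality, Life Expectancy Gaps and Lifespan Disparity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying how much of the life expectancy and
    lifespan disparity gap between two groups of countries is attributable
    to avoidable (preventable and treatable) mortality. Provides abridged
    period life tables with e0 and the e-dagger lifespan disparity measure,
    classification of ICD-10 causes of death against an editable
    OECD/Eurostat-style avoidability list, counterfactual cause-deleted and
    rate-substitution life tables, linear integral (Horiuchi) decomposition
    of differences in e0 and e-dagger into additive age-by-cause
    contributions, a reader for WHO Mortality Database style count files,
    and a Gompertz-Makeham synthetic-data generator with known ground truth
    for validation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
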