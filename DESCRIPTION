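Package: equilife
Title: Deaths Averted, Life Expectancy and Lifespan Inequality under
    Child-Health Intervention Scale-Up
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scenario-based projection of child-health intervention
    coverage scale-up. Provides a cause-specific lives-saved cascade over
    an ordered intervention package (preventive before curative, with
    subcomponent handling), abridged period life tables with Chiang life
    expectancy at birth, under-five and maternal mortality adjustments to
    the life table, and the extended Gini coefficient of inequality in
    age at death with inequality-aversion parameter v. Includes a
    synthetic Ethiopia-like baseline generator, a packaged deaths-averted
    reference table, and writers for coverage, mortality and equity
    trajectory reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
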