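Package: spaflood
Title: Supply-Demand Hydraulic Modelling of Stomatal Responses to Soil
    Waterlogging
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing stomatal responses of tree seedlings to soil
    waterlogging. Implements a soil-plant-atmosphere (SPA) supply-demand
    hydraulic model with Weibull xylem vulnerability curves and a
    flood-duration-dependent impairment of whole-plant hydraulic conductance;
    vacuum-chamber and leaf-level hydraulic conductance calculations;
    shared-intercept treatment-by-duration linear models with Type II
    interaction tests, repeated-measures mixed-model likelihood-ratio tests,
    Spearman correlation matrices and logistic dose-response (ED50) fits for
    hypertrophied lenticels; recursive path analysis with maximum-likelihood
    estimation, AICc ranking, Akaike weights and multimodel coefficient
    averaging; and a synthetic greenhouse-experiment generator that emulates
    the experimental design so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
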