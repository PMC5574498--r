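Package: mastagree
Title: Inter-Method Agreement Analysis for Multiple Allergen Simultaneous Tests
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Concordance analysis between semi-quantitative allergen-specific
    IgE panel analyzers (multiple allergen simultaneous tests, MAST). Builds
    matched (patient, allergen) pairs between two analyzers, dichotomizes
    class 0-6 results at a configurable cutoff, and computes total agreement
    percentage, concordant positive rate, Cohen's kappa with delta-method
    standard error and normal-approximation confidence interval, and a signed
    directional discordance statistic ("positive propensity"). Includes cutoff
    sweeps, per-analyzer positivity profiles, multi-positive-per-patient
    summaries, a synthetic paired-data generator with target kappa and
    propensity, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
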