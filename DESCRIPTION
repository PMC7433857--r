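Package: sslscore
Title: Semantic Storage Loss Scoring for Primary Progressive Aphasia
Version: 0.1.0
Authors@R:
    person("sslscore", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Computes the semantic storage loss (SSL) score, a three-component
    composite quantifying the degree of semantic storage impairment in
    individuals with anomia: the proportion of naming failures recovered with
    a phonemic cue, the consistency between naming failures and word-picture
    matching, and the ratio of naming performance to general cognition (MMSE).
    Includes normative cut-off screening (mean minus k standard deviations),
    validation statistics (one-way ANOVA with Scheffe post hoc tests, Pearson
    correlations, hierarchical regression with an R-squared-change F test),
    a simulator for item-level patient cohorts with coupled regional
    FDG-uptake ratios, and a command-line interface over CSV cohort files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
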