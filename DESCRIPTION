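Package: cohortbridge
Title: Census-Mortality Linkage Correction and Coding-Change Adjustment for
    Register-Based Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for register-based mortality cohorts built by linking
    census records to a national death registry. Implements a pragmatic
    two-step rule-based allocation of unlinked death certificates to census
    records (with impossible-match rules and random tie-breaking), exact
    person-time (Lexis) computation by calendar year, sex and attained-age
    group, mortality rate tables including versus excluding unlinked deaths
    with comparison to midyear-population reference rates, a Poisson trend
    model with restricted cubic splines and a step term quantifying a
    cause-of-death coding-policy change as a multiplication factor, and
    piecewise-exponential hazard-ratio comparisons. A synthetic census and
    death-registry generator with known ground truth supports evaluation of
    every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
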