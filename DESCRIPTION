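Package: bouted
Title: Bouted Physical Activity Outcomes and Delay-Control Trial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives bouted physical-activity outcomes (moderate-to-vigorous,
    purposeful, and sedentary bouts) from minute-epoch wearable accelerometry,
    estimates intervention effects in delay-control (waitlist) randomized trials
    via baseline-adjusted ANCOVA and longitudinal random-intercept mixed models
    with cluster-robust (sandwich) standard errors, scores intervention-fidelity
    criteria, and ships a synthetic-trial generator with known ground truth so
    the whole pipeline is testable end to end without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
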