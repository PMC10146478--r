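Package: virtualcontrols
Title: Virtual Control Groups for School-Based Prevention Trial Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs algorithmically generated comparison groups ("virtual
    controls") for school-based substance-use prevention trials that lack a
    randomized control condition. Provides tools to code psychosocial survey
    items onto a 0-10 scale and average them into a psych score, to build
    age-by-percentile normative tables of psych scores smoothed by
    per-percentile quadratic curves, to calibrate logistic probability-of-use
    weights from treatment pretest data, to peg each treated student to the
    normative percentile that best matches their pretest age and psych score,
    and to compare treatment self-reports against virtual-control probability
    estimates at the student, classroom, and school level, including
    demographic subgroup z-tests. A synthetic-data module generates normative
    pools and nested longitudinal trial cohorts with attrition so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
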