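Package: limbscreen
Title: Lower-Limb Arterial Screening Strategies and Diagnostic Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating non-invasive screening strategies for
    lower-limb peripheral arterial disease (PAD). Implements the
    ankle-brachial and toe-brachial indices, a targeted test-selection rule
    that screens with the toe-brachial index in patients with diabetes,
    renal disease or advanced age, and the American Heart Association
    guideline rule that substitutes the toe-brachial index only when the
    ankle-brachial index exceeds 1.4. Participants are labelled against a
    colour duplex ultrasound reference standard (any artery with more than
    50 percent stenosis), and each strategy's sensitivity, specificity,
    predictive values, likelihood ratios and diagnostic accuracy are
    reported with exact binomial (Clopper-Pearson) and log-method
    likelihood-ratio confidence intervals. Includes a calibrated synthetic
    cohort generator with a medial arterial calcification mechanism, and a
    brute-force oracle that recovers 2x2 contingency tables from printed
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), withr, yaml, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
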