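Package: scenetime
Title: Time-Course Analysis of Semantic and Spatial Scene Categorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the temporal dynamics of rapid scene
    categorization in backward-masked, m-alternative forced-choice
    experiments. Implements the generalized m-AFC d-prime of the unbiased
    max-rule observer (forward model and numerical inversion), per-condition
    sensitivity time-courses and stereo effects, leave-one-out ceiling
    performance from time-unlimited labelling pools, inter-observer-agreement
    binning with shared-weight normalization and bootstrap trial
    equalization, conditional-probability causal models that predict one
    category system from responses in the other, multinomial
    decision-variable correlation with pairwise and leave-one-out
    human-human references, Cohen's kappa and mutual information, and a
    seeded synthetic-observer simulator that emulates the full
    within-subject design so every analysis can be exercised end-to-end
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
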