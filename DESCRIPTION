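Package: vbtvalid
Title: Concurrent Validity of Barbell Velocity Measurement Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for concurrent-validity studies of barbell velocity
    measurement systems in velocity-based resistance training. Simulates
    cohorts of powerlifters, criterion (motion-capture style) barbell
    trajectories and practical-device observations with known bias and
    error structure; reproduces criterion signal processing (zero-phase
    Butterworth filtering, differentiation, threshold-based repetition
    detection); pairs criterion and practical observations with missed-
    and ghost-repetition bookkeeping; fits Bayesian linear mixed models
    with correlated random intercepts and slopes to derive proportional
    bias, standardized mean bias, root mean squared error and R2 with 95%
    highest density intervals; and classifies devices against a
    reference-device-anchored region of practical equivalence (ROPE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rjags,
    coda,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
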