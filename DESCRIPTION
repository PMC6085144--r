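Package: painlaw
Title: Power-Law Modelling of Pain Recovery Trajectories
Version: 0.1.0
Authors@R:
    person("OSS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Fits time-dependent power laws to longitudinal pain-intensity
    records (numerical rating scale, 0-10), projects future pain from early
    time marks under four projection schemes, characterizes chronicity via
    the half-reduction ratio M = 2^(1/P), imputes missing interior time
    marks by linear and power-law interpolation, and compares power-law
    against exponential decay for cohort mean trajectories via chi-square.
    Includes a seeded synthetic-cohort generator (power-law mean
    trajectories with additive Gaussian noise, clamped to the rating
    scale), an exponential-decay ensemble generator with a gamma rate
    mixture and its closed-form aggregate, a single-subject case-study
    workflow converting medication-dose histories to a no-medication pain
    proxy, and a command-line pipeline producing deterministic JSON
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
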