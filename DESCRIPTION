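Package: promcat
Title: Computerized Adaptive Testing for High-Frequency Patient-Reported
    Outcome Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A computational engine for administering patient-reported
    outcome measures (PROMs) as computerized adaptive tests (CAT) on an
    ecological momentary assessment (EMA) schedule.  Implements graded
    response model numerics (category probabilities, likelihoods, Fisher
    information), expected a posteriori (EAP) scoring on a quadrature
    grid, minimum expected posterior variance and maximum-information
    item selection with optional randomesque exposure control,
    SE-threshold stopping rules, and dynamic priors that carry the
    posterior of one assessment forward as the prior of the next.
    Includes a schedule and respondent simulator for thrice-weekly,
    daily, and thrice-daily EMA regimes with clinically motivated latent
    symptom trajectories, individual-level uncertainty analytics (95%
    credible bands, posterior density surfaces, LOESS smoothing with a
    t-based standard error band, cohort-context overlays), and CSV
    round-trip readers and writers plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
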