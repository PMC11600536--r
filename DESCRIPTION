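Package: mhtemulate
Title: Emulated Target Trials of Menopausal Hormone Therapy and
    Cardiovascular Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for emulating a sequence of monthly nested target trials
    of menopausal hormone therapy (MHT) initiation from linked prescription,
    diagnosis and procedure registries.  Provides a synthetic registry
    generator with known treatment effects and configurable confounding,
    trial-month eligibility screening with washout, eight-arm treatment
    strategy classification from dispensation records, treatment-episode
    construction with a grace-period extension rule, stabilized inverse
    probability of treatment and censoring weights, and weighted
    cause-specific Cox and Fine-Gray estimation with cluster-robust
    variance, adjusted cumulative incidence curves and incidence rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    jsonlite,
    withr
Config/testthat/edition: 3
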