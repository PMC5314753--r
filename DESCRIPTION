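Package: mhplan
Title: Mental Health Burden, Service Scale-Up and Avertable Burden Modelling
    for Conflict-Affected Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning age-standardised prevalence estimates of major
    depression and post-traumatic stress disorder into planning quantities for
    conflict-affected populations: prevalent cases with comorbidity adjustment,
    years lived with disability (YLD) with Monte-Carlo uncertainty intervals,
    mhGAP-style human-resource and service scale-up requirements over a 15-year
    horizon, and multi-cohort Markov (illness-death) health-benefit analyses of
    the disease burden avertable under increasing treatment coverage. Includes a
    synthetic-population generator (pyramid, Gompertz-Makeham mortality,
    calibrated age-specific prevalence curves) so the full pipeline runs
    offline, and a DisMod-2-style solver that back-calculates internally
    consistent incidence from prevalence, remission and mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
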