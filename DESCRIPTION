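Package: stillavert
Title: Deterministic Deaths-Averted Modelling of Stillbirth Intervention Scale-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the reduction in antepartum and intrapartum stillbirths
    achievable by scaling up coverage of eight health interventions, in the
    linear deterministic style of the Lives Saved Tool (LiST). Ships the
    published effectiveness estimates, population-attributable affected
    fractions and coverage-proxy defaults as an overridable registry, projects
    multi-year coverage scenarios against a country stillbirth envelope, and
    validates the deterministic arithmetic against an individual-level
    Monte-Carlo pregnancy cohort simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
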