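Package: abxtimeout
Title: Automated Antibiotic Time-Out Alerts and Stewardship Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an automated day-5 antibiotic time-out for
    antimicrobial stewardship: rule-based detection of inpatients reaching
    five days of continuous therapy on targeted antimicrobials from dose
    administration records, monthly consumption metrics (mean duration of
    therapy and days of therapy per 1000 patient-days), segmented
    interrupted-time-series regression of intervention effects with a
    contemporaneous control group, and Poisson incidence-rate-ratio trend
    analysis of healthcare-associated infection rates. Includes a synthetic
    electronic-health-record event-stream generator so the full pipeline is
    reproducible without institutional data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
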