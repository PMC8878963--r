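Package: adlwatch
Title: Unobtrusive Activity Monitoring from Smart-Meter Appliance Usage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the regularity of instrumental activities of daily living
    (cooking, laundry, ...) of a household occupant from the usage of
    hand-operated appliances visible in smart-meter power traces. Provides a
    synthetic-household generator with controlled anomaly injection
    (divergent usage time, night usage, absence), threshold-based appliance
    state derivation and activation extraction, a combinatorial-optimisation
    load-disaggregation baseline, daily activity curves scored against an
    observation database with a weighted Jensen-Shannon divergence, an
    inter-quantile-range decision rule with per-day anomaly classification,
    external-agent feedback integration with a replacement (forgetting)
    policy, and end-to-end evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
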