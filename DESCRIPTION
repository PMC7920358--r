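Package: margaytrap
Title: Long-Term Camera-Trap By-Catch Analysis for Cryptic Felids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the population status of a cryptic,
    individually identifiable felid from long-term camera-trap by-catch.
    Implements individual-level detection accounting (daily independence
    filtering, flank-based minimum/maximum individual counts, trap-night
    tallies and location-years), dynamic multi-season occupancy models
    (initial occupancy, colonization, extinction, detection) with
    QAICc model selection and a parametric-bootstrap overdispersion
    estimate, circular kernel activity-overlap estimation with bootstrap
    confidence intervals, effort-detection analyses, movement and range
    proxies (maximum distance moved, circular range areas), dyad
    interaction summaries, tenure and minimum-age estimation, and an
    individual-based camera-trap survey simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
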