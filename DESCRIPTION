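Package: forearmspa
Title: Secular Trends in Pediatric Forearm Bone Traits from Single-Photon Absorptiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-photon absorptiometry (SPA) forearm line scans for
    synthetic two-cohort pediatric studies, recovers bone mineral content and
    bone widths from the scan traces, derives cylindrical-bone strength indices
    (cross-sectional moment of inertia, section modulus, strength index), applies
    phantom-based instrument drift correction, and fits log-linear age-trajectory
    models with age-by-cohort interactions to compare trait trajectories across
    cohorts measured decades apart. Includes a reproducible end-to-end pipeline,
    broom-style tidiers for fitted trend models, and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
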