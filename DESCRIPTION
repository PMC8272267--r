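Package: fptstop
Title: First-Passage-Time Stopover Detection and Weather-Response
    Analysis for Migratory Tracking Data
Version: 0.1.0
Authors@R:
    person("Movement Ecology", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments hourly-interpolated GPS tracks of migratory soaring
    birds into stopovers using first passage time (FPT) with a
    variance-based per-migration radius and threshold, applies the
    duration, daylight, endpoint-trimming, roost-start and buffer-rescue
    rules used in fine-scale stopover studies, aligns hourly weather
    changes to stopover starts and ends, and fits the two companion mixed
    models (stopover counts per migration and a binomial GLMM for
    proportion of activity). Includes a correlated-random-walk track and
    weather simulator with known ground truth so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
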