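Package: affectrhythm
Title: Lexicon-Based Affective States and Diurnal Mood Rhythms from Social
    Media Postings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures sentiment and emotion in time-stamped social-media
    postings with word-list dictionaries (LIWC-style), aggregates token and
    match counts per user and clock hour, and derives per-user-hour affect
    probabilities, user baselines, relative probabilities and population
    diurnal rhythm curves. Provides composite positive sentiment and
    positive emotion scores, covariate coding for epidemiological
    regression (age bands, BMI classes, sex-role classes, log-transformed
    network counts), univariate screening followed by multivariate linear
    regression with permutation-based p-values (response and Freedman-Lane
    schemes), Cohen's kappa for inter-rater theme coding, and a seeded
    synthetic-corpus generator with hour-dependent token emission and
    known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
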