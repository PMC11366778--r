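Package: equicross
Title: Equipercentile Crosswalks Between Cognitive Screening Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates score conversion tables (crosswalks) between
    two bounded integer cognitive screening instruments, with the Rowland
    Universal Dementia Assessment Scale (RUDAS) to Mini-Mental State
    Examination (MMSE) conversion as the worked case. Implements discrete
    equipercentile equating with log-linear presmoothing of the score
    distributions, continuity-corrected percentile ranks and their inverses,
    rounding of the equated function into a monotone integer crosswalk, and
    agreement validation via the two-way random-effects intraclass correlation
    coefficient, Pearson correlation, and within-k-point agreement rates.
    Ships the published RUDAS-to-MMSE conversion table as a package resource
    and a latent-Gaussian mixture simulator for paired bounded test scores in
    mixed healthy-control and early-stage Alzheimer's disease cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
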