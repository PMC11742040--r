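Package: devodrift
Title: Comparing Developmental Trajectories of Serial Organs Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for comparing the developmental dynamics of
    serial organs (upper/lower molars, fore/hindlimbs) between species.
    Provides continuous-time Markov inference of morphological stage
    durations from cross-sectional staged-embryo collections (with
    Erlang-expanded stages and nested rate-class model selection), embryo
    weight-to-age chronology calibration with monotone smoothers and
    milestone-based relative timelines, nested negative-binomial spline
    models of expression time courses with a decision-tree classification
    and a transcriptome coevolution index, windowed expression-profile
    distances, marker-gene tissue deconvolution of bulk samples with
    bootstrap intervals, and seeded synthetic-data generators emulating
    each input so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    MASS,
    mgcv,
    splines,
    stats,
    graphics,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
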