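Package: flashtrace
Title: Flash Pattern and Flight Path Analysis for Time-Lapse Video of
    Bioluminescent Organisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts per-individual bioluminescent flash signals and
    flight paths from time-lapse video of flashing organisms such as
    fireflies. Loads AVI video or numbered frame stacks, tracks
    individuals either from manual trace files or by automated spot
    detection with nearest-neighbour linking, measures
    background-corrected region-of-interest photometry, segments the
    intensity traces into flash events, and quantifies
    species-characteristic pattern metrics (flash duration, peak
    interval, interflash interval, sub-pulse structure). Also provides
    pairwise cross-correlation synchrony, periodogram spectra of flash
    trains, box-counting fractal dimension of flight paths, rendered
    orbit-line figures with stepped intensity circles, overlay video
    export, and a ground-truthed synthetic scene simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    readr,
    yaml,
    jsonlite,
    ggplot2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
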