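Package: mycomorph
Title: Quantitative Morphometrics of Filamentous Microorganisms in
    Mono- and Coculture Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for the quantitative morphology of
    filamentous fungi and actinomycetes grown in stirred-tank bioreactors,
    alone or in coculture.  Segments phase-contrast micrographs (median
    smoothing, Sobel edges, Otsu thresholding, connected components with
    declarative operator overrides), computes per-object shape descriptors
    (projected area, Crofton perimeter, Feret diameters, circularity,
    elongation and the morphology number Mo = sqrt(C)/E), splits objects
    into fully evolved pellets versus hyphae and clumps with species
    attribution, summarises populations per sampling time with Student-t
    confidence bands and Welch t-tests against monoculture controls, and
    calls the coculture outcome (morphological domination, advantage, or
    none), optionally corroborated by aeration/stirring process-profile
    similarity.  Ships a synthetic phase-contrast scene generator with
    per-object ground truth so the whole pipeline is testable without
    micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    EBImage,
    tiff,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
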