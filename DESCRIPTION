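Package: flfaquant
Title: Wavelet-Based Detection and Quantification of Weak Fluorescence
    Signals on Lateral-Flow-Assay Strip Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies weak, low-contrast fluorescence bands and
    spots on filter-free lateral-flow-assay (FLFA) strip images. Projection
    profiles are denoised and contrast-enhanced with a Mexican Hat (Ricker)
    continuous wavelet transform; peaks are located by first-derivative
    zero crossings, delimited by their flanking troughs, validated by a
    trough-separation threshold, and quantified by per-scan-line baseline-
    subtracted integration into an average-pixel statistic. Includes
    four-parameter logistic calibration, a seeded synthetic strip/dot-matrix
    image generator with analytic ground truth, and a command-line pipeline.
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
    minpack.lm,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
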