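Package: ebt3dose
Title: Radiochromic Film Dosimetry Read-Out with Flatbed-Scanner Corrections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-out system for Gafchromic EBT3 radiochromic film dosimetry
    with a flatbed transmission scanner. Implements lossless 48-bit RGB TIFF
    film-scan handling, a two-phase scanner sensitivity correction (per-pixel
    additive matrix correction from unexposed-film stacks plus an iterative
    dose-dependent transversal correction from constant-dose stripe scans),
    net-optical-density to absorbed-dose calibration with a rational response
    function, a four-orientation flipped read-out protocol with dust rejection
    and mean-dose merging, film and timing quality-control rules, and a
    quadrature uncertainty-budget calculator. A synthetic scanner/film
    simulator generates ground-truth-paired fixtures so the whole pipeline is
    testable without scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
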