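Package: ihcscore
Title: Quantitative Scoring of DAB-Stained Immunohistochemistry Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated, quantitative scoring of brightfield
    immunohistochemistry (IHC) micrographs stained with DAB chromogen and
    hematoxylin counterstain. Images are unmixed by color de-convolution
    into per-stain optical-density channels; the pure-DAB intensity
    histogram is partitioned into four intensity zones that map to the
    standard 0/1+/2+/3+ grades, with a majority-zone dominance rule and a
    zone-weighted scoring formula. Also provides pathologist-style
    stained-area categories, a seeded synthetic IHC image generator with
    ground-truth grades for validation, and cohort-level statistics
    (percent agreement, Cohen's kappa, 2x2 chi-square tests, stratified
    positivity summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    e1071,
    jsonlite
Config/testthat/edition: 3
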