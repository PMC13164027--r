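Package: ihcallred
Title: DAB-Intensity Nucleus Classification and Allred Scoring for IHC Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An auditable pipeline for quantifying nuclear hormone-receptor
    expression in chromogenic immunohistochemistry (IHC) images. Separates
    hematoxylin and DAB stains by optical-density deconvolution under the
    Beer-Lambert model, computes a per-nucleus inverted mean DAB statistic
    on externally supplied or internally generated instance masks, classifies
    nuclei into Strong/Moderate/Weak/Negative intensity grades with
    calibratable thresholds (grid-search maximisation of macro-F1 on an
    annotated calibration table), and aggregates the four-class counts into
    the clinical Allred score (proportion score P, intensity score I, total
    P+I and a treatment recommendation). Includes mask postprocessing (small
    object removal, hole filling, fragment merging), pixel- and nucleus-level
    evaluation metrics, and a seeded synthetic tile generator with known
    ground truth so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
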