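Package: periplaque
Title: Peri-Plaque Histology Quantification for Amyloid Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification of amyloid plaque pathology and the peri-plaque
    glial response in multi-channel fluorescence microscopy of brain
    sections. Segments Abeta plaques by intensity thresholding with
    physical-unit size filtering, classifies plaques as dense-core,
    fibrillar or mixed from relative Abeta/thioflavin S intensity, builds
    fixed-width peri-plaque band regions by exact Euclidean distance
    transform, and computes GFAP enrichment ratios, microglial perimeter
    coverage, neuronal Abeta-puncta uptake, presynaptic dystrophy counts
    and AQP4 polarization ratios. Includes a synthetic multi-channel scene
    generator with planted ground truth for end-to-end validation, and
    per-animal aggregation with the group comparisons used in histology
    studies (unpaired t-tests, two-way ANOVA with Bonferroni post-tests,
    cumulative frequency distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
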