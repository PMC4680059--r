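Package: cdi
Title: Cartilage Damage Index for the Lateral Tibiofemoral Compartment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rapid quantification of articular cartilage damage in the lateral
    tibiofemoral compartment from segmented knee MRI. Builds a rectangular
    universal coordinate system over the femoral and tibial articular surfaces,
    accumulates a denudation frequency atlas across knees, selects informative
    measurement locations, and scores a height-normalized cartilage damage
    index (CDI) from cartilage thickness and anterior-posterior extent at those
    locations. Includes a synthetic phantom and cohort generator with known
    ground truth, and the validation statistics used for such imaging
    biomarkers: ICC(3,1) intra-rater reliability, standardized response mean,
    Spearman correlation, and the Jonckheere-Terpstra ordered trend test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
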