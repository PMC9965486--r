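Package: choriomap
Title: Choriocapillaris Flow-Deficit Quantification from OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow deficits in en-face optical
    coherence tomography angiography (OCTA) slabs. Implements axial-length
    magnification correction (Littmann ratio form of the modified Bennett
    formula), Phansalkar local adaptive binarization, the choriocapillaris
    flow area (CCFA) ratio, and a tile-grid coefficient-of-variation
    heterogeneity statistic, together with region-masked and banded
    within-eye comparisons, dual-cutoff risk classification, and
    cohort-level nonparametric and logistic inference. Calibrated synthetic
    image and cohort generators allow every stage to be validated
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
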