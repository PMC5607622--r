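Package: hequant
Title: Semi-Automated Quantification of Hard Exudates in Colour Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and area measurement of hard exudates (HEs) in colour
    fundus photographs of eyes with diabetic retinopathy. Implements a
    two-pronged pipeline -- morphological white top-hat filtering, contrast
    limited adaptive histogram equalization and fixed thresholding run once
    on the grayscale image (bright exudates) and once on the green plane
    (faint exudates) -- combined by union, with scripted rectangular outlier
    exclusion and mm^2 area reporting. Also provides a maximum-entropy
    (Kapur) green-plane thresholding baseline for method comparison,
    observer-agreement statistics (uncentered correlation, Bland-Altman
    limits of agreement, intraclass correlation), and a seeded synthetic
    fundus scene generator with per-class ground-truth masks so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    ggplot2,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
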