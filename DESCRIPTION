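Package: gliaquant
Title: Unbiased Area-Fraction Quantification of Perinatal White Matter Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies astrogliosis (GFAP) and microgliosis (Iba1) in
    immunofluorescence sections as a continuous stained-area fraction using a
    histogram-reflection background-subtraction algorithm: the background peak
    is located from the three highest-frequency histogram bins, the
    background-side area is integrated and doubled, and the remainder of the
    region is the labeled area. The package embeds the quantifier in a fully
    seeded desk-scale pipeline that simulates a fetal sheep hypoxia-ischemia
    cohort (epoch physiology, latent injury severity, synthetic section images
    with ground truth, ordinal necrosis scores) and recovers the hemodynamic
    and metabolic associations of injury severity with covariate-adjusted
    least-squares statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
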