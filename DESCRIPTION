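Package: fsuaxial
Title: Reduced-Order Axial Compression Analysis of Bone-Disc-Bone Spinal Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico replication of quasi-static axial compression
    experiments on functional spinal units (bone-disc-bone specimens).
    Implements Holzapfel-type anisotropic hyperelasticity for the annulus
    fibrosus, Mooney-Rivlin incompressible elasticity for the nucleus pulposus
    and greyscale-mapped linear elasticity for vertebral bone; a reduced-order
    series/parallel forward model of a specimen under displacement-controlled
    compression; a seeded synthetic cohort generator for four treatment groups
    (control, bone plug, nucleotomy, hydrogel-augmented); a continuous
    tri-linear stress/strain fit yielding three effective Young's moduli and
    two transition strains; and the statistical comparison layer (normality
    gating, ANOVA or Kruskal-Wallis, pairwise t-tests, variance F-tests,
    least-squares regression and Lin's concordance correlation coefficient).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
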