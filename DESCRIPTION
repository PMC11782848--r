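Package: fafquant
Title: Quantification of Fundus Autofluorescence Features in Inherited
    Retinal Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based segmentation and quantitative analysis of fundus
    autofluorescence (FAF) imaging features in inherited retinal disease:
    optic disc, hypo- and hyper-autofluorescence, perimacular ring, and
    vessels.  Provides fovea-centric geometry (distance maps, 0.5 mm
    annulus profiles, fixed-radius areas, ring angular completeness),
    per-feature morphometrics (presence, area, connected components,
    brightness, vessel density), Dice and presence/absence agreement
    validation, a cohort pipeline (quality-control filtering, per-day
    deduplication, first-presentation aggregation by gene and age group,
    per-eye progression slopes, ABCA4 severity and RPGR region grouping),
    and a synthetic FAF phantom generator with exact ground-truth masks
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
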