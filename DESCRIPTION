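Package: palatwin
Title: Palatal Morphometrics and Classical Twin Variance-Component Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark- and mesh-based measurement of palatal morphology from
    digital maxillary dental casts (gingival, mid-palatal and posterior plane
    construction, plane-clipped surface area and volume, widths, depths and
    antero-posterior length), together with classical monozygotic/dizygotic
    twin variance-component modelling (ACE/ADE family) by maximum likelihood,
    with likelihood-ratio and AIC model selection, profile-likelihood
    confidence intervals and narrow-sense heritability. Includes generators
    for synthetic palate meshes with known ground-truth dimensions and for
    twin cohorts with zygosity-structured covariance, so the full pipeline is
    testable without any subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
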