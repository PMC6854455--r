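Package: copeSets
Title: Spatial Confidence Sets for Raw Effect Size Excursion Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs simultaneous spatial confidence sets that bracket,
    with confidence 1 - alpha, the excursion set where a general-linear-model
    contrast of raw effect size (e.g. percent BOLD change) exceeds a
    threshold. The critical value is obtained by a wild multiplier bootstrap
    (Gaussian or Rademacher multipliers, plain or studentized) of the
    supremum of the error field over a sub-voxel linearly interpolated
    level-set boundary. Includes a synthetic-data framework (ramp, circle
    and sphere phantoms with smoothed Gaussian noise) and Monte-Carlo
    machinery that validates empirical coverage by both direct lattice
    comparison and interpolated boundary assessment, plus NIfTI input/output
    for group-level neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    rlang,
    tibble,
    dplyr,
    ggplot2,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
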