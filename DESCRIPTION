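Package: boldica
Title: Tumor Tissue Detection from Resting-State BOLD fMRI by Spatial ICA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tumor-affected tissue in resting-state BOLD fMRI by
    repeated individual-level spatial independent component analysis across a
    swept model order, with automatic tumor-component identification by the
    Discriminability-Index-based Component Identification (DICI) statistic
    z(HR) - z(FAR) against a rough binary tumor template. Includes an
    intensity-based 3D region-growth template generator, a RAICAR-style
    run-averaging scheme for reproducible components, a seed-correlation
    baseline, and a synthetic lesion-bearing 4D BOLD phantom generator with
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ica,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
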