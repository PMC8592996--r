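Package: spineload
Title: Sex-Specific Static Musculoskeletal Estimation of Lumbar Spinal Loads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simplified static musculoskeletal model of the trunk for
    estimating L5-S1 compression and shear during static manual material
    handling tasks. The rigid-body spine chain (pelvis, five lumbar
    vertebrae, thorax) is posed from trunk-pelvis angles distributed to
    intervertebral joints by a lumbar rhythm; muscle redundancy is resolved
    by minimizing the sum of cubed muscle stresses under per-joint moment
    equilibrium, with an intra-abdominal pressure actuator capped at
    26.6 kPa. Model variants carry sex-specific muscle cross-sectional
    areas, segmental mass fractions and body-fat scaling. Includes an EMG
    envelope pipeline (band-pass, rectification, low-pass, MVC
    normalization), a synthetic-trial generator with known ground truth,
    and a study battery with paired/unpaired comparisons between male,
    female base and female-specific model variants.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
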