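Package: pennemg
Title: Forward Simulation of Surface EMG for Pennate Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator of differential-electrode surface
    electromyograms (sEMG) for pennate skeletal muscle, parameterised for
    the human Tibialis Anterior. Single-fibre action potentials are built
    from the Rosenfalck intracellular potential and its transmembrane
    current, conducted through an anisotropic volume-conductor kernel that
    accommodates fibre pennation, and superposed over a Fuglevand-style
    motor-unit pool with size-principle recruitment and linear rate coding.
    Includes the signal features used to validate such models (windowed
    RMS, median frequency, Higuchi fractal dimension) and an equivalence
    testing layer (two-sample t-test, Bland-Altman limits, TOST).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
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
RoxygenNote: 7.3.3
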