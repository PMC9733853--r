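Package: wristhar
Title: Activity Recognition for Electrical Line Worker Tasks from a
    Wrist-Worn Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for recognising ten common electrical
    line worker tasks from a single wrist-worn tri-axial accelerometer
    sampled at 32 Hz. Provides a synthetic-cohort generator emulating the
    statistical structure of the task classes (static gravity
    orientations, gait-band periodicity, high-dispersion hoisting),
    plain-text recording input/output, non-overlapping windowing (4 s and
    10 s), three feature domains (filtered-signal statistics, truncated
    FFT magnitudes, Daubechies-4 wavelet band statistics), k-nearest
    neighbour, support vector machine and random forest classifiers under
    intra- and inter-subject evaluation protocols, two-way ANOVA with
    Tukey HSD model comparison, and interpretation tools: random forest
    importance, local surrogate (LIME-style) class explanations and
    inverse-transform signal reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    ranger,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
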