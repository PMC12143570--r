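Package: burstfusion
Title: Multisensory Burst-Detection Tasks and Temporal Fusion Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-alternative multisensory detection task in which a
    hidden target emits bursts of direction-informative signals of fixed,
    uniform or heavy-tailed (Levy) length against a noisy background, with the
    per-step burst-start probability normalised so that the expected signal
    sparsity is constant across task variants. Implements the closed-form
    sparsity normalisation and its numerical inversion, a family of
    count-feature fusion classifiers (linear fusion, nonlinear fusion, and
    sliding-window nonlinear fusion) fitted by regularised logistic regression,
    a recurrent neural network sequence classifier trained by backpropagation
    through time, a brute-force Bayes posterior oracle for tiny trials, and an
    experiment harness for in-distribution, out-of-distribution and
    mixed-burst-length accuracy grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    Matrix,
    glmnet,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    withr
Config/testthat/edition: 3
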