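Package: wienerfit
Title: Diffusion Model Analysis of Binary-Choice Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Wiener diffusion models to response times and accuracies
    from fast binary decision tasks. Provides exact series representations of
    first-passage-time densities, a finite-difference solver for predicted
    cumulative distributions, three fit criteria (maximum likelihood,
    chi-square, Kolmogorov-Smirnov), a penalized Nelder-Mead simplex search
    with EZ-based initialization and staged restarts, a control-file driven
    batch interface, and companion tools for simulating data sets, exporting
    predicted distributions, and Monte-Carlo calibration of model-fit
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
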