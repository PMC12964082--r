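Package: handtrans
Title: Gene-Culture Transmission Models of Human Handedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and evaluates a gene-culture co-evolutionary model of human
    hand-preference transmission. Implements the fixed right-shift-allele
    transmission model (genetic effect rho, cultural effects alpha and beta),
    its equilibrium incidence of left-handedness, a criterion-shift
    misclassification adjustment mapping true to measured incidences via
    parent and offspring transition matrices (M = P T O), binomial
    maximum-likelihood estimation under three analysis scenarios with
    multi-start Nelder-Mead and grid-search validation, G-test goodness-of-fit
    for familial and twin data, a sex-difference model family compared by
    likelihood-ratio tests, and a simulation harness quantifying estimator
    bias, mean squared error and bootstrap confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
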