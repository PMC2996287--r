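Package: zipfheaps
Title: Zipf's Law, Heaps' Law and Their Finite-Size Relation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative machinery connecting Zipf's rank-frequency law to
    Heaps' vocabulary-growth law in finite-size systems. Provides exponent
    conversions between rank-based and density-based power laws, the
    finite-size analytical relation between system size and the number of
    distinct elements (with an improved discrete-normalization variant and a
    Lambert-W closed form for the unit Zipf exponent), least-squares and
    maximum-likelihood exponent estimators, a rank-driven stochastic
    occurrence simulator with power-law, exponential-cutoff and exponential
    profiles, plain-text readers and writers for event streams and
    rank-frequency tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
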