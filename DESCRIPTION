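Package: qrprates
Title: Replication Rates and False Positive Rates Under P-Hacking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the expected replication rate and false positive rate of
    published significant results as a function of the base rate of true
    effects, nominal significance levels, and statistical power, and models how
    four questionable research practices (selective reporting of studies,
    failing to report all dependent measures, data peeking, and selective
    outlier removal) inflate the effective Type 1 error rate and power of an
    original study. Effective rates for the first three practices are obtained
    analytically from multivariate normal orthant and box probabilities;
    selective outlier removal is evaluated by Monte-Carlo simulation of
    contaminated-normal data. An agent-level Monte-Carlo oracle re-derives
    every analytic quantity by direct simulation for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
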