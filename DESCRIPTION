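Package: raterfit
Title: Detecting Biased OSCE Raters with the lz Person-Fit Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo machinery for studying how well the standardized
    log-likelihood person-fit statistic (lz) detects stringent and lenient
    raters in a station-based clinical examination (OSCE). Provides a packaged
    checklist item bank with a classical-test-theory to two-parameter-logistic
    conversion, vectorized 2PL response simulation and maximum-likelihood
    ability estimation, entry-level rater bias injection, per-rater lz
    computation with normal-reference flagging, and a factorial power-study
    harness (detection and false-positive rates, balanced three-way ANOVA
    with partial eta squared).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
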