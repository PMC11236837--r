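Package: ilrpower
Title: Compositional Analysis of Bipolar Likert Scales and Power of
    Correlation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for treating bipolar Likert-scale responses as two-part
    compositional data. Builds response scales adjusted for a limit of
    quantification (LOQ), implements the log-ratio transform family (alr,
    clr, logit and the isometric log-ratio transform with its inverse),
    enumerates the discrete lattice of achievable item-mean values, and
    snaps continuous scores to that lattice. Includes heavy-tailed
    bivariate samplers (elliptical Laplace and Cauchy) and a Monte-Carlo
    engine that compares the statistical power of the Pearson correlation
    t-test on ilr-transformed versus raw response scales across large
    scenario grids, with Table-style aggregation of the power difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
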