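Package: wntopsis
Title: Entropy-Weight TOPSIS Evaluation of Water and Nitrogen Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates factorial irrigation-by-nitrogen field trials end to
    end: computes crop water consumption from layered gravimetric
    soil-moisture records by soil-water balance, derives water- and
    nitrogen-use efficiency indices (WUE, IWUE, NPFP), screens redundant
    indicators by Pearson correlation, and ranks treatments with an
    entropy-weighted TOPSIS closeness score. Ships the printed indicator
    tables of a two-season deficit-irrigation eggplant trial as plain-text
    fixtures, a seeded synthetic-trial generator with known response
    surfaces for pipeline validation, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
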