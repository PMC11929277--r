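Package: textnorm
Title: Rule-Based Normalization of Free-Text Data Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage, user-rule-driven engine for normalizing columns of
    free-text data items such as the subject-age and data-location fields of
    curated biomedical databases. Variance is addressed at three levels:
    characters, words, and phrases. Character and word rules are authored
    iteratively through a review/reference TSV cycle of action decisions
    (replace_with, remove, invalidate, allow); phrases are categorized into
    pattern strings and rewritten into standard forms by a user-defined
    phrase-type ruleset. Includes an accessory splitter for list-like items
    (figure/table enumerations), per-item Levenshtein change metrics and
    stage validity rates, a synthetic corpus generator with ground-truth
    canonical forms, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
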