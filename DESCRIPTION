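Package: ctopic
Title: Comparative Topic Scoring Between Positive- and Negative-Result Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrastive keyword analysis between two document
    collections reporting divergent results on the same research question.
    Every term occurring in the "positive" corpus is scored by the arithmetic
    mean of its proportional occurrence across both corpora and its document
    distribution within the positive corpus; candidate determinant terms are
    then selected by a strict proportional-occurrence filter, a score
    percentile filter, and membership in a user-supplied lexicon. Includes a
    text normalization pipeline (tokenization, lowercasing, punctuation
    stripping, stopword removal, dictionary lemmatization), a classical
    TF-IDF mean-ranking baseline, a synthetic two-corpus generator with
    planted signal terms for validation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
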