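test_that("load_lexicon normalizes entries and applies set semantics", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# nutritional compounds", "Zeaxanthin", "Copper", "copper",
               "Nitrates", ""), path)
  lex <- load_lexicon(path)
  expect_s3_class(lex, "ctopic_lexicon")
  expect_identical(lex$entries, c("copper", "nitrate", "zeaxanthin"))
  expect_length(lex$dropped_multiword, 0)
})

test_that("multiword lexicon entries are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Ascorbic acid", "Copper"), path)
  expect_warning(lex <- load_lexicon(path), "multiword")
  expect_identical(lex$entries, "copper")
  expect_identical(lex$dropped_multiword, "Ascorbic acid")
})

test_that("empty or unusable lexicon files error", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# just a comment"), path)
  expect_error(load_lexicon(path), "empty")
  expect_error(load_lexicon(file.path(tempdir(), "missing-lex.txt")), "exist")
})

test_that("percentile threshold uses linear interpolation over all scores", {
  expect_equal(percentile_threshold(c(0, 0.25, 0.5, 0.75, 1), 75), 0.75)
  expect_equal(percentile_threshold(rep(0.4, 10), 75), 0.4)
  expect_equal(percentile_threshold(c(0, 1), 75), 0.75)
  expect_error(percentile_threshold(numeric(0), 75), "non-empty")
})

make_stats <- function(terms, b, score) {
  tibble::tibble(term = terms, n_pos = 1L, n_total = 2L, b = b,
                 doc_count_pos = 1L, n_docs_pos = 2L,
                 dist_fraction = 2 * score - b, score = score)
}

test_that("all three filters are strict and composable in any order", {
  stats <- make_stats(
    c("x", "y", "z", "w", "v"),
    b = c(0.9, 0.4, 0.9, 0.51, 0.9),
    score = c(0.9, 0.9, 0.2, 0.9, 0.88)
  )
  lex <- lexicon(c("x", "y", "z", "v"), plain_config())
  cfg <- selection_config(percentile = 20, min_proportion = 0.5)
  sel <- select_determinants(stats, lex, cfg)
  # y fails b-filter despite high score; z fails score filter;
  # w passes b and score but is not in the lexicon
  expect_identical(sel$term, c("x", "v"))
  expect_true(all(sel$selected))
  thr <- attr(sel, "threshold")
  expect_equal(thr, percentile_threshold(stats$score, 20))
  # each selected term satisfies the three predicates when re-checked
  for (t in sel$term) {
    row <- stats[stats$term == t, ]
    expect_gt(row$b, cfg$min_proportion)
    expect_gt(row$score, thr)
    expect_true(t %in% lex$entries)
  }
  # strictness: a term exactly at a bound is excluded
  at_bound <- make_stats(c("p", "q"), b = c(0.5, 1), score = c(1, 0.9))
  sel2 <- suppressMessages(
    select_determinants(at_bound, lexicon(c("p", "q"), plain_config()),
                        selection_config(percentile = 50))
  )
  expect_false("p" %in% sel2$term)  # passes the score cut but b == 0.5 exactly
})

test_that("filter application order does not change the selected set", {
  set.seed(21)
  stats <- make_stats(
    sprintf("t%02d", 1:40),
    b = round(runif(40), 2),
    score = round(runif(40), 2)
  )
  stats$dist_fraction <- pmin(1, pmax(0, stats$dist_fraction))
  lex_terms <- sample(stats$term, 20)
  lex <- lexicon(lex_terms, plain_config())
  cfg <- selection_config()
  sel <- select_determinants(stats, lex, cfg)
  thr <- percentile_threshold(stats$score, cfg$percentile)
  # manual re-composition in every one of the 6 orders
  preds <- list(
    b = stats$b > cfg$min_proportion,
    s = stats$score > thr,
    l = stats$term %in% lex$entries
  )
  for (ord in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    keep <- rep(TRUE, nrow(stats))
    for (i in ord) keep <- keep & preds[[i]]
    expect_setequal(sel$term, stats$term[keep])
  }
})

test_that("raising either knob never grows the selected set", {
  set.seed(5)
  stats <- make_stats(
    sprintf("t%02d", 1:60),
    b = round(runif(60), 2),
    score = round(runif(60), 2)
  )
  lex <- lexicon(stats$term, plain_config())
  prev <- NULL
  for (p in c(25, 50, 75, 90)) {
    cur <- select_determinants(stats, lex, selection_config(percentile = p))$term
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (m in c(0.2, 0.5, 0.7, 0.9)) {
    cur <- select_determinants(stats, lex,
                               selection_config(min_proportion = m))$term
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("empty selection is a valid, reported outcome", {
  stats <- make_stats(c("a", "b"), b = c(0.1, 0.2), score = c(0.3, 0.4))
  lex <- lexicon(c("a", "b"), plain_config())
  expect_message(sel <- select_determinants(stats, lex), "no terms")
  expect_identical(nrow(sel), 0L)
  expect_identical(unname(attr(sel, "filter_counts")["selected"]), 0L)
})

test_that("lexicon requirement can be disabled", {
  stats <- make_stats(c("a", "b", "c", "d"), b = c(0.9, 0.9, 0.9, 0.1),
                      score = c(0.9, 0.88, 0.1, 0.9))
  cfg <- selection_config(percentile = 25, require_lexicon = FALSE)
  sel <- select_determinants(stats, NULL, cfg)
  expect_identical(sel$term, c("a", "b"))
  expect_error(select_determinants(stats, NULL, selection_config()), "lexicon")
})
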