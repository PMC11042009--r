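test_that("build_test_set is the exact union of positive-corpus token sets", {
  docs <- norm_corpus(list(c("a", "b"), c("b", "c")))
  expect_identical(build_test_set(docs), c("a", "b", "c"))
  # empty document contributes nothing
  docs2 <- norm_corpus(list(character(0), "x"))
  expect_identical(build_test_set(docs2), "x")
  expect_error(build_test_set(norm_corpus(list())), "empty")
})

test_that("proportional occurrence is the exact cross-corpus ratio", {
  pos <- c(zinc = 3L, copper = 5L, shared = 1L)
  neg <- c(zinc = 1L, shared = 1L)
  expect_equal(proportional_occurrence("zinc", pos, neg), 0.75)
  expect_equal(proportional_occurrence("copper", pos, neg), 1.0)
  expect_equal(proportional_occurrence("shared", pos, neg), 0.5)
  expect_error(proportional_occurrence("absent", pos, neg), "neither corpus")
})

test_that("distribution fraction counts documents, not occurrences", {
  docs <- norm_corpus(list(rep("zinc", 50), c("copper", "iron")))
  expect_equal(distribution_fraction("zinc", docs), 0.5)
  expect_equal(distribution_fraction("copper", docs), 0.5)
  expect_equal(distribution_fraction("absent", docs), 0)
  nine <- norm_corpus(rep(list("zinc"), 9))
  expect_equal(distribution_fraction("zinc", nine), 1)
})

test_that("score_term is the arithmetic mean with [0,1] domain checks", {
  expect_equal(score_term(1, 1), 1)
  expect_equal(score_term(0.8, 1), 0.9)
  expect_equal(score_term(0.5, 0), 0.25)
  expect_error(score_term(1.2, 0.5), "must be in")
  expect_error(score_term(0.5, -0.1), "must be in")
})

test_that("score_terms matches the hand-count example", {
  # Cp = {"x x y"}, Cn = {"y"}
  stats <- score_terms(norm_pair(list(c("x", "x", "y")), list("y")))
  x <- stats[stats$term == "x", ]
  y <- stats[stats$term == "y", ]
  expect_equal(x$b, 1); expect_equal(x$dist_fraction, 1); expect_equal(x$score, 1)
  expect_equal(y$b, 0.5); expect_equal(y$dist_fraction, 1); expect_equal(y$score, 0.75)
  expect_identical(x$n_pos, 2L); expect_identical(y$n_total, 2L)
})

test_that("disjoint vocabularies give b = 1 for every positive term", {
  stats <- score_terms(norm_pair(list(c("a", "b"), c("b", "c")), list(c("q", "r"))))
  expect_true(all(stats$b == 1))
  expect_equal(stats$score, (1 + stats$dist_fraction) / 2)
})

test_that("all statistics match an independent brute-force recount on random corpora", {
  set.seed(42)
  alphabet <- letters[1:12]
  for (i in 1:300) {
    pos <- random_token_lists(sample.int(5, 1), 20, alphabet)
    neg <- random_token_lists(sample.int(5, 1), 20, alphabet)
    got <- as.data.frame(score_terms(norm_pair(pos, neg)))
    want <- oracle_term_stats(pos, neg)
    got <- got[order(got$term), ]
    rownames(got) <- NULL
    expect_identical(got$term, want$term)
    expect_identical(got$n_pos, want$n_pos)
    expect_identical(got$n_total, want$n_total)
    expect_identical(got$doc_count_pos, want$doc_count_pos)
    expect_identical(got$b, want$b)            # exact ratios, no tolerance
    expect_identical(got$dist_fraction, want$dist_fraction)
    expect_identical(got$score, want$score)
  }
})

test_that("scores are bounded and 1 exactly for ubiquitous positive-exclusive terms", {
  set.seed(7)
  for (i in 1:50) {
    pos <- random_token_lists(sample.int(4, 1), 15, letters[1:8])
    neg <- random_token_lists(sample.int(4, 1), 15, letters[5:12])
    stats <- score_terms(norm_pair(pos, neg))
    expect_true(all(stats$score >= 0 & stats$score <= 1))
    is_one <- stats$score == 1
    should_be_one <- stats$b == 1 & stats$dist_fraction == 1
    expect_identical(is_one, should_be_one)
  }
})

test_that("score is strictly monotone in each component at the other fixed", {
  bs <- seq(0, 1, by = 0.1)
  for (d in c(0, 0.4, 1)) {
    expect_true(all(diff(vapply(bs, score_term, numeric(1), dist_fraction = d)) > 0))
    expect_true(all(diff(vapply(bs, score_term, numeric(1), b = d)) > 0))
  }
})

test_that("statistics are invariant to document order", {
  set.seed(11)
  pos <- random_token_lists(5, 20, letters[1:10])
  neg <- random_token_lists(4, 20, letters[1:10])
  base <- score_terms(norm_pair(pos, neg))
  for (i in 1:5) {
    shuffled <- score_terms(norm_pair(sample(pos), sample(neg)))
    expect_identical(shuffled, base)
  }
})

test_that("duplicating every positive document leaves b and dist unchanged", {
  set.seed(3)
  pos <- random_token_lists(3, 20, letters[1:10])
  neg <- random_token_lists(3, 20, letters[1:10])
  base <- score_terms(norm_pair(pos, neg))
  doubled <- score_terms(norm_pair(c(pos, pos), neg))
  m <- match(base$term, doubled$term)
  expect_identical(doubled$dist_fraction[m], base$dist_fraction)
  # raw counts double in Cp, so b shifts toward 1 -- the scale invariance
  # under duplication holds for dist; for b it holds when Cn is duplicated too
  both <- score_terms(norm_pair(c(pos, pos), c(neg, neg)))
  m2 <- match(base$term, both$term)
  expect_identical(both$b[m2], base$b)
  expect_identical(both$dist_fraction[m2], base$dist_fraction)
  expect_identical(both$score[m2], base$score)
})
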