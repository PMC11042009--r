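# Shared fixtures and independent brute-force oracles.

# Config that isolates counting behaviour from stopword/lemmatizer effects.
plain_config <- function() {
  preprocess_config(stopwords = character(0), lemmatizer = "identity")
}

# Build a normalized document directly from a token vector.
norm_doc <- function(tokens, doc_id = "doc") {
  structure(
    list(doc_id = doc_id, tokens = tokens, raw_word_count = length(tokens)),
    class = "ctopic_normalized_document"
  )
}

norm_corpus <- function(token_lists, label = "positive") {
  ids <- names(token_lists) %||% sprintf("d%02d", seq_along(token_lists))
  docs <- Map(norm_doc, token_lists, ids)
  structure(unname(docs), label = label, class = "ctopic_normalized_corpus")
}

norm_pair <- function(pos_token_lists, neg_token_lists) {
  structure(
    list(positive = norm_corpus(pos_token_lists, "positive"),
         negative = norm_corpus(neg_token_lists, "negative")),
    class = "ctopic_normalized_pair"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force recount of every term statistic by explicit nested loops
# over raw token lists; deliberately naive and independent of score_terms().
oracle_term_stats <- function(pos_tokens, neg_tokens) {
  terms <- character(0)
  for (d in pos_tokens) for (t in d) {
    if (!t %in% terms) terms <- c(terms, t)
  }
  terms <- sort(terms, method = "radix")
  rows <- list()
  for (t in terms) {
    n_pos <- 0L
    for (d in pos_tokens) for (w in d) if (w == t) n_pos <- n_pos + 1L
    n_neg <- 0L
    for (d in neg_tokens) for (w in d) if (w == t) n_neg <- n_neg + 1L
    dc <- 0L
    for (d in pos_tokens) {
      present <- FALSE
      for (w in d) if (w == t) present <- TRUE
      if (present) dc <- dc + 1L
    }
    b <- n_pos / (n_pos + n_neg)
    dist <- dc / length(pos_tokens)
    rows[[t]] <- data.frame(
      term = t, n_pos = n_pos, n_total = n_pos + n_neg, b = b,
      doc_count_pos = dc, n_docs_pos = length(pos_tokens),
      dist_fraction = dist, score = (b + dist) / 2,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Brute-force TF-IDF scorer for one document in a toy corpus.
oracle_tfidf_ranks <- function(doc_tokens, corpus_token_lists, base = exp(1)) {
  terms <- sort(unique(doc_tokens), method = "radix")
  f <- vapply(terms, function(t) sum(doc_tokens == t), integer(1))
  df <- vapply(terms, function(t) {
    sum(vapply(corpus_token_lists, function(d) any(d == t), logical(1)))
  }, integer(1))
  score <- f * log(length(corpus_token_lists) / df, base = base)
  ord <- order(-score, -f, terms, method = "radix")
  data.frame(term = terms[ord], tfidf = score[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

# Random toy corpus: n docs of up to max_len tokens over a small alphabet.
random_token_lists <- function(n_docs, max_len, alphabet) {
  lapply(seq_len(n_docs), function(i) {
    sample(alphabet, sample.int(max_len, 1), replace = TRUE)
  })
}

write_corpus_dir <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(docs)) {
    writeLines(docs[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  dir
}
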