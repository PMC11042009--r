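# Classical TF-IDF baseline: per-document term rankings within one corpus
# and cross-corpus mean ranks, used to contextualize the determinant
# scores. Only rank positions matter downstream, which makes the rankings
# invariant to the logarithm base.

#' TF-IDF score of a term in a document
#'
#' `tf(t, d) = f(t, d) * log(|D| / DF(t))` with the natural logarithm,
#' where `f` is the raw in-document frequency, `n_docs` the corpus size and
#' `df` the number of corpus documents containing the term.
#'
#' @param f Raw count of the term in the document (vectorized).
#' @param n_docs Number of documents in the corpus.
#' @param df Document frequency of the term in the corpus (vectorized).
#' @param base Logarithm base; default `exp(1)`. Rankings do not depend on
#'   it.
#' @return Numeric score(s).
#' @export
#' @examples
#' tfidf_score(5, 10, 2)  # 5 * log(5)
tfidf_score <- function(f, n_docs, df, base = exp(1)) {
  check_scalar_number(n_docs, "n_docs", 1)
  stopifnot(is.numeric(f), is.numeric(df), length(f) == length(df))
  if (any(f < 0) || any(df < 0) || any(df > n_docs)) {
    abort("need 0 <= df <= n_docs and f >= 0")
  }
  if (any(df == 0 & f > 0)) {
    abort("inconsistent counts: term occurs (f > 0) but df = 0")
  }
  out <- numeric(length(f))
  pos <- f > 0
  out[pos] <- f[pos] * log(n_docs / df[pos], base = base)
  out
}

# Document frequency of every corpus term, computed once per corpus.
corpus_document_frequencies <- function(corpus_docs) {
  tab <- table(unlist(lapply(corpus_docs, function(d) unique(d$tokens)),
                      use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Rank the terms of one document by TF-IDF
#'
#' Scores every distinct term of the document against the given corpus and
#' assigns dense ranks 1, 2, ... (1 = most prominent). Ties on score are
#' broken by higher raw frequency first, then alphabetically. Terms absent
#' from the document receive no rank.
#'
#' @param doc A `ctopic_normalized_document` belonging to `corpus_docs`.
#' @param corpus_docs The normalized corpus used for document frequencies.
#' @param base Logarithm base passed to [tfidf_score()].
#' @return A tibble `term`, `f`, `df`, `tfidf`, `rank`, ordered by rank;
#'   zero rows for an empty document.
#' @export
rank_document_terms <- function(doc, corpus_docs, base = exp(1)) {
  stopifnot(inherits(doc, "ctopic_normalized_document"))
  corpus_docs <- as_norm_docs(corpus_docs, "corpus_docs")
  n_docs <- length(corpus_docs)
  if (n_docs == 0L) abort("corpus must contain at least one document")
  if (length(doc$tokens) == 0L) {
    return(tibble::tibble(term = character(), f = integer(), df = integer(),
                          tfidf = numeric(), rank = integer()))
  }
  f_tab <- table(doc$tokens)
  terms <- names(f_tab)
  f <- as.integer(f_tab)
  df_counts <- corpus_document_frequencies(corpus_docs)
  df <- as.integer(count_of(df_counts, terms))
  score <- tfidf_score(f, n_docs, df, base = base)
  ord <- order(-score, -f, terms, method = "radix")
  tibble::tibble(
    term = terms[ord], f = f[ord], df = unname(df[ord]),
    tfidf = score[ord], rank = seq_along(ord)
  )
}

#' Mean TF-IDF rank of a term across one corpus
#'
#' For each corpus document containing the term, the term's dense TF-IDF
#' rank within that document is taken; the result is the arithmetic mean of
#' those ranks. A term contained in no document has no mean rank (`NA`),
#' mirroring the "N/A" convention for corpus-absent terms.
#'
#' @param term Normalized term.
#' @param corpus_docs Normalized corpus.
#' @param base Logarithm base.
#' @return Mean rank, or `NA_real_` if the term occurs nowhere in the
#'   corpus.
#' @export
mean_rank <- function(term, corpus_docs, base = exp(1)) {
  check_string(term, "term")
  corpus_docs <- as_norm_docs(corpus_docs, "corpus_docs")
  if (length(corpus_docs) == 0L) abort("corpus must contain at least one document")
  ranks <- numeric(0)
  for (d in corpus_docs) {
    if (term %in% d$tokens) {
      rk <- rank_document_terms(d, corpus_docs, base = base)
      ranks <- c(ranks, rk$rank[rk$term == term])
    }
  }
  if (length(ranks) == 0L) return(NA_real_)
  mean(ranks)
}

#' Cross-corpus mean TF-IDF rank table
#'
#' Runs the three-step mean-ranking procedure for a set of terms: rank each
#' positive-corpus document's terms by TF-IDF (document frequency from the
#' positive corpus), do the same for the negative corpus, and average each
#' term's rank over the documents that contain it, per corpus.
#'
#' @param terms Character vector of normalized terms of interest.
#' @param pair A `ctopic_normalized_pair`.
#' @param base Logarithm base.
#' @return A tibble `term`, `mean_rank_pos`, `mean_rank_neg` (`NA` where
#'   the term is absent from that corpus), in the input term order.
#' @export
mean_rank_table <- function(terms, pair, base = exp(1)) {
  stopifnot(is.character(terms))
  if (length(terms) == 0L) abort("no terms requested for TF-IDF mean ranking")
  pos_docs <- as_norm_docs(pair$positive, "pair$positive")
  neg_docs <- as_norm_docs(pair$negative, "pair$negative")
  rank_map <- function(docs) {
    lapply(docs, function(d) {
      rk <- rank_document_terms(d, docs, base = base)
      setNames(rk$rank, rk$term)
    })
  }
  mean_from <- function(maps, term) {
    ranks <- unlist(lapply(maps, function(m) unname(m[term])), use.names = FALSE)
    ranks <- ranks[!is.na(ranks)]
    if (length(ranks) == 0L) NA_real_ else mean(ranks)
  }
  pos_maps <- rank_map(pos_docs)
  neg_maps <- rank_map(neg_docs)
  tibble::tibble(
    term = terms,
    mean_rank_pos = unname(vapply(terms, mean_from, numeric(1), maps = pos_maps)),
    mean_rank_neg = unname(vapply(terms, mean_from, numeric(1), maps = neg_maps))
  )
}
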