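# Core comparative statistics: for every term of the positive-corpus test
# set, the proportional occurrence b(t) across both corpora, the document
# distribution fraction within the positive corpus, and their arithmetic
# mean, the determinant score a(t) in [0, 1].

as_norm_docs <- function(x, what) {
  if (inherits(x, "ctopic_normalized_corpus")) return(unclass_keep(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ctopic_normalized_document"))) {
    return(x)
  }
  abort(sprintf("`%s` must be a normalized corpus or list of normalized documents", what))
}

unclass_keep <- function(x) {
  attributes(x) <- list(names = names(x))
  x
}

#' Build the test set: unique terms of the positive corpus
#'
#' The scored vocabulary is the exact set union of the token sets of all
#' positive-corpus documents; no frequency threshold is applied, and terms
#' occurring only in the negative corpus are never scored.
#'
#' @param pos_docs Normalized positive corpus
#'   (see [normalize_corpus()]).
#' @return Sorted character vector of unique terms.
#' @export
build_test_set <- function(pos_docs) {
  pos_docs <- as_norm_docs(pos_docs, "pos_docs")
  if (length(pos_docs) == 0L) abort("test set undefined for an empty corpus")
  sort(unique(unlist(lapply(pos_docs, function(d) d$tokens), use.names = FALSE)),
       method = "radix")
}

term_counts <- function(docs) {
  tokens <- unlist(lapply(docs, function(d) d$tokens), use.names = FALSE)
  if (length(tokens) == 0L) return(integer(0))
  tab <- table(tokens)
  setNames(as.integer(tab), names(tab))
}

count_of <- function(counts, term) {
  v <- counts[term]
  ifelse(is.na(v), 0L, v)
}

#' Proportional occurrence of a term in the positive corpus
#'
#' `b(t) = n(t, Cp) / (n(t, Cp) + n(t, Cn))`: the fraction of all raw
#' occurrences of the term, across both corpora, that fall in the positive
#' corpus. Counts are raw multiset totals with no per-document capping.
#'
#' @param term Normalized term.
#' @param pos_counts,neg_counts Named integer vectors of per-term occurrence
#'   totals for each corpus (e.g. from internal counting, or supplied
#'   directly).
#' @return Proportion in \[0, 1\].
#' @export
proportional_occurrence <- function(term, pos_counts, neg_counts) {
  check_string(term, "term")
  n_pos <- count_of(pos_counts, term)
  n_total <- n_pos + count_of(neg_counts, term)
  if (n_total == 0L) {
    abort(sprintf(
      "proportional occurrence undefined: '%s' occurs in neither corpus", term
    ))
  }
  as.numeric(n_pos) / as.numeric(n_total)
}

#' Document distribution fraction of a term in the positive corpus
#'
#' The number of positive-corpus documents containing the term at least
#' once, divided by the number of positive-corpus documents. Documents are
#' counted, not occurrences: fifty mentions inside one document still count
#' as one document.
#'
#' @param term Normalized term.
#' @param pos_docs Normalized positive corpus.
#' @return Proportion in \[0, 1\].
#' @export
distribution_fraction <- function(term, pos_docs) {
  check_string(term, "term")
  pos_docs <- as_norm_docs(pos_docs, "pos_docs")
  if (length(pos_docs) == 0L) abort("distribution undefined for an empty corpus")
  in_doc <- vapply(pos_docs, function(d) term %in% d$tokens, logical(1))
  sum(in_doc) / length(pos_docs)
}

#' Determinant score of a term
#'
#' The arithmetic mean of the proportional occurrence and the document
#' distribution fraction: `a(t) = (b(t) + DCp(t)/DCp) / 2`, ranging from 0
#' to 1. Higher values flag terms both disproportionately present in, and
#' consistently distributed across, the positive corpus.
#'
#' @param b Proportional occurrence in \[0, 1\].
#' @param dist_fraction Document distribution fraction in \[0, 1\].
#' @return Score in \[0, 1\].
#' @export
score_term <- function(b, dist_fraction) {
  check_scalar_number(b, "b", 0, 1)
  check_scalar_number(dist_fraction, "dist_fraction", 0, 1)
  (b + dist_fraction) / 2
}

#' Score every test-set term of a normalized corpus pair
#'
#' Computes, for each term of the positive corpus' unique vocabulary, the
#' raw counts in each corpus, the proportional occurrence `b`, the document
#' distribution fraction, and the determinant score. Exact integer
#' numerators and denominators are kept alongside the floating-point ratios
#' so consumers can re-derive them at full precision.
#'
#' @param pair A `ctopic_normalized_pair` from [normalize_corpus()], or a
#'   list with normalized `positive` and `negative` elements.
#' @return A tibble with one row per test-set term: `term`, `n_pos`,
#'   `n_total`, `b`, `doc_count_pos`, `n_docs_pos`, `dist_fraction`,
#'   `score`; sorted by score descending, term ascending.
#' @export
score_terms <- function(pair) {
  pos_docs <- as_norm_docs(pair$positive, "pair$positive")
  neg_docs <- as_norm_docs(pair$negative, "pair$negative")
  if (length(pos_docs) == 0L || length(neg_docs) == 0L) {
    abort("both corpora must contain at least one document")
  }
  terms <- build_test_set(pos_docs)
  if (length(terms) == 0L) {
    return(tibble::tibble(
      term = character(), n_pos = integer(), n_total = integer(),
      b = numeric(), doc_count_pos = integer(), n_docs_pos = integer(),
      dist_fraction = numeric(), score = numeric()
    ))
  }
  pos_counts <- term_counts(pos_docs)
  neg_counts <- term_counts(neg_docs)
  n_docs_pos <- length(pos_docs)
  # document frequency within the positive corpus
  doc_sets <- lapply(pos_docs, function(d) unique(d$tokens))
  df_tab <- table(unlist(doc_sets, use.names = FALSE))
  doc_count_pos <- as.integer(count_of(setNames(as.integer(df_tab), names(df_tab)), terms))

  n_pos <- as.integer(count_of(pos_counts, terms))
  n_total <- n_pos + as.integer(count_of(neg_counts, terms))
  b <- as.numeric(n_pos) / as.numeric(n_total)
  dist_fraction <- doc_count_pos / n_docs_pos
  tibble::tibble(
    term = terms,
    n_pos = n_pos,
    n_total = n_total,
    b = b,
    doc_count_pos = doc_count_pos,
    n_docs_pos = n_docs_pos,
    dist_fraction = dist_fraction,
    score = (b + dist_fraction) / 2
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$term)
}
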