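# Text normalization: tokenize -> lowercase -> strip punctuation ->
# remove stopwords -> lemmatize. Each document becomes a multiset of
# normalized terms; raw word counts are taken on the untouched text.

#' Default English stopword list
#'
#' The frozen stopword file shipped with the package (standard English NLP
#' stopword list): one lowercase token per line, `#` comments allowed.
#'
#' @param path Optional path to an alternative stopword file in the same
#'   format.
#' @return Character vector of stopword tokens.
#' @export
default_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords_en.txt",
                                package = "ctopic", mustWork = TRUE)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(lines)
  lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
}

#' Normalization pipeline configuration
#'
#' Immutable settings for the document normalization pipeline. Tokens are
#' maximal runs of letters and digits; hyphens internal to a token are kept
#' by default so compound names such as "omega-3" survive as single terms.
#'
#' @param stopwords Character vector of lowercase stopword tokens. Default:
#'   the shipped English list ([default_stopwords()]).
#' @param lemmatizer `"dictionary"` (rule-plus-exception English
#'   lemmatization, the default) or `"identity"` (no lemmatization; useful
#'   for tests and non-English corpora).
#' @param keep_internal_hyphens Keep hyphens between alphanumeric runs, so
#'   "omega-3" is one token? Default `TRUE`.
#' @param strip_digits Drop tokens consisting solely of digits? Default
#'   `FALSE` (standalone numerals are kept).
#' @return A `ctopic_preprocess_config` list.
#' @export
preprocess_config <- function(stopwords = default_stopwords(),
                              lemmatizer = c("dictionary", "identity"),
                              keep_internal_hyphens = TRUE,
                              strip_digits = FALSE) {
  lemmatizer <- match.arg(lemmatizer)
  stopifnot(is.character(stopwords), is.logical(keep_internal_hyphens),
            is.logical(strip_digits))
  if (any(stopwords != tolower(stopwords))) {
    abort("stopword list entries must already be lowercase")
  }
  structure(
    list(
      stopwords = stopwords,
      lemmatizer = lemmatizer,
      keep_internal_hyphens = isTRUE(keep_internal_hyphens),
      strip_digits = isTRUE(strip_digits)
    ),
    class = "ctopic_preprocess_config"
  )
}

#' @export
print.ctopic_preprocess_config <- function(x, ...) {
  cat(sprintf(
    "<ctopic_preprocess_config> lemmatizer=%s, %d stopwords, hyphens=%s, strip_digits=%s\n",
    x$lemmatizer, length(x$stopwords),
    if (x$keep_internal_hyphens) "keep" else "split", x$strip_digits
  ))
  invisible(x)
}

# Tokenization -----------------------------------------------------------

tokenize_text <- function(text, config) {
  pattern <- if (config$keep_internal_hyphens) {
    "[[:alnum:]]+(?:-[[:alnum:]]+)*"
  } else {
    "[[:alnum:]]+"
  }
  tokens <- stringr::str_extract_all(stringr::str_to_lower(text), pattern)[[1]]
  if (config$strip_digits) {
    tokens <- tokens[!stringr::str_detect(tokens, "^[0-9]+$")]
  }
  tokens
}

# Lemmatization ----------------------------------------------------------

# Exception table shipped with the package, cached per session.
the <- new.env(parent = emptyenv())

lemma_exceptions <- function() {
  if (is.null(the$lemma_exceptions)) {
    path <- system.file("extdata", "lemma_exceptions.tsv",
                        package = "ctopic", mustWork = TRUE)
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
    parts <- stringr::str_split_fixed(lines, "\t", 2)
    the$lemma_exceptions <- setNames(parts[, 2], parts[, 1])
  }
  the$lemma_exceptions
}

# One rule-cascade pass over a single lowercase token. English inflection
# rules: irregulars via the exception table; plural noun endings; regular
# -ied/-ing/-ed verb endings with consonant undoubling. A token a rule
# cannot confidently reduce is returned unchanged.
lemmatize_once <- function(w) {
  exc <- lemma_exceptions()
  hit <- exc[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  if (n < 4L) return(w)
  end3 <- substr(w, n - 2L, n)
  end4 <- if (n >= 4L) substr(w, n - 3L, n) else ""

  undouble <- function(stem) {
    m <- nchar(stem)
    if (m >= 2L) {
      last2 <- substr(stem, m - 1L, m)
      c1 <- substr(last2, 1L, 1L)
      if (c1 == substr(last2, 2L, 2L) &&
          !last2 %in% c("ll", "ss", "ff", "zz") &&
          !stringr::str_detect(c1, "[aeiou]")) {
        return(substr(stem, 1L, m - 1L))
      }
    }
    stem
  }

  # plural nouns
  if (end4 == "sses") return(substr(w, 1L, n - 2L))            # glasses -> glass
  if (end3 == "ies") {
    if (n >= 5L) return(paste0(substr(w, 1L, n - 3L), "y"))    # studies -> study
    return(substr(w, 1L, n - 1L))                              # ties -> tie
  }
  if (end3 %in% c("xes", "zes") || end4 %in% c("ches", "shes")) {
    return(substr(w, 1L, n - 2L))                              # boxes -> box
  }
  # regular verb forms
  if (end3 == "ied" && n >= 5L) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (end3 == "ing" && n >= 6L) {
    stem <- substr(w, 1L, n - 3L)
    if (stringr::str_detect(stem, "[aeiouy]")) return(undouble(stem))
    return(w)                                                  # string, spring
  }
  if (substr(w, n - 1L, n) == "ed" && n >= 5L) {
    if (end3 == "eed") return(w)                               # proceed, speed
    stem <- substr(w, 1L, n - 2L)
    if (stringr::str_detect(stem, "[aeiouy]")) return(undouble(stem))
    return(w)
  }

  # generic plural: drop final s unless the singular-looking endings ss/us/is
  if (substr(w, n, n) == "s" &&
      !substr(w, n - 1L, n) %in% c("ss", "us", "is")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}

#' Lemmatize normalized tokens
#'
#' Dictionary-based English lemmatization: an exception table of irregular
#' forms plus suffix rules for regular plurals and -ed/-ing inflection,
#' iterated to a fixed point so the mapping is idempotent. Tokens the rules
#' cannot confidently reduce pass through unchanged.
#'
#' @param tokens Character vector of lowercase, punctuation-free tokens.
#' @param mode `"dictionary"` or `"identity"`.
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
#' @examples
#' lemmatize(c("researched", "researching", "nitrates", "acids"))
lemmatize <- function(tokens, mode = c("dictionary", "identity")) {
  mode <- match.arg(mode)
  if (mode == "identity" || length(tokens) == 0L) return(tokens)
  uniq <- unique(tokens)
  mapped <- vapply(uniq, function(w) {
    for (i in 1:5) {
      w2 <- lemmatize_once(w)
      if (identical(w2, w)) break
      w <- w2
    }
    w
  }, character(1))
  unname(mapped[match(tokens, uniq)])
}

# Document normalization -------------------------------------------------

#' Normalize one document to a multiset of terms
#'
#' Applies the pipeline tokenize, lowercase, punctuation stripping, stopword
#' removal, lemmatization. The raw word count is the whitespace-token count
#' of the untouched text, recorded before any filtering.
#'
#' @param text Raw document text (single string).
#' @param doc_id Document identifier.
#' @param config A [preprocess_config()].
#' @return A list of class `ctopic_normalized_document` with fields
#'   `doc_id`, `tokens` (character vector, one element per occurrence) and
#'   `raw_word_count`.
#' @export
normalize_document <- function(text, doc_id = "doc", config = preprocess_config()) {
  stopifnot(inherits(config, "ctopic_preprocess_config"))
  if (length(text) != 1L || is.na(text)) abort("`text` must be a single string")
  raw_word_count <- length(stringr::str_split_1(stringr::str_trim(text), "\\s+")) *
    (nchar(stringr::str_trim(text)) > 0)
  tokens <- tokenize_text(text, config)
  tokens <- tokens[!tokens %in% config$stopwords]
  tokens <- lemmatize(tokens, config$lemmatizer)
  structure(
    list(doc_id = doc_id, tokens = tokens, raw_word_count = raw_word_count),
    class = "ctopic_normalized_document"
  )
}

#' @export
print.ctopic_normalized_document <- function(x, ...) {
  cat(sprintf(
    "<normalized document '%s'> %d retained token(s), %d raw word(s)\n",
    x$doc_id, length(x$tokens), x$raw_word_count
  ))
  invisible(x)
}

#' Normalize every document of a corpus
#'
#' @param x A `ctopic_corpus` or `ctopic_corpus_pair`.
#' @param config A [preprocess_config()].
#' @return For a corpus: a list of `ctopic_normalized_document` (class
#'   `ctopic_normalized_corpus`, `label` attribute preserved). For a pair: a
#'   list with normalized `positive` and `negative` elements (class
#'   `ctopic_normalized_pair`).
#' @export
normalize_corpus <- function(x, config = preprocess_config()) {
  if (inherits(x, "ctopic_corpus_pair")) {
    out <- list(
      positive = normalize_corpus(x$positive, config),
      negative = normalize_corpus(x$negative, config)
    )
    return(structure(out, class = "ctopic_normalized_pair"))
  }
  stopifnot(inherits(x, "ctopic_corpus"))
  docs <- purrr::map2(x$text, x$doc_id, normalize_document, config = config)
  structure(docs, label = attr(x, "label"),
            class = "ctopic_normalized_corpus")
}

#' Raw word count of a normalized corpus
#'
#' Sum of whitespace-token counts of the raw documents, the corpus "combined
#' length in words".
#'
#' @param docs A `ctopic_normalized_corpus` (or plain list of normalized
#'   documents).
#' @return Integer word count.
#' @export
corpus_word_count <- function(docs) {
  as.integer(sum(vapply(docs, function(d) d$raw_word_count, numeric(1))))
}

#' Normalize a standalone term
#'
#' Applies exactly the document pipeline to a free-standing string, as used
#' for lexicon entries. A term may normalize to zero tokens (a stopword),
#' one token, or several (a multiword compound name).
#'
#' @param term Non-empty string.
#' @param config A [preprocess_config()].
#' @return Character vector of normalized tokens (possibly empty).
#' @export
#' @examples
#' normalize_term("Zeaxanthin")
#' normalize_term("Ascorbic acid")
normalize_term <- function(term, config = preprocess_config()) {
  check_string(term, "term")
  normalize_document(term, doc_id = "term", config = config)$tokens
}
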