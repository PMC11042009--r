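# Candidate selection: the three filters applied to scored terms —
# strict proportional-occurrence cut (b > 0.5), strict score cut at a
# percentile of the full score distribution (default 75th), and membership
# in a lexicon of candidate terms.

#' Load a candidate-term lexicon
#'
#' Reads a one-term-per-line UTF-8 file (`#` comments allowed) and
#' normalizes each entry through the same pipeline as the documents, so
#' lexicon and corpus terms match on normalized forms. Entries that
#' normalize to more than one token (multiword compound names) cannot match
#' a unigram vocabulary and are dropped with a warning; entries that
#' normalize to nothing (stopwords) are dropped silently. Duplicates
#' collapse to one entry.
#'
#' @param path Lexicon file path.
#' @param config A [preprocess_config()]; must match the one used on the
#'   corpora.
#' @return A `ctopic_lexicon` list with `entries` (sorted unique normalized
#'   single tokens) and `dropped_multiword` (the source lines that
#'   normalized to several tokens).
#' @export
load_lexicon <- function(path, config = preprocess_config()) {
  check_string(path, "path")
  if (!file.exists(path)) abort(sprintf("lexicon file does not exist: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0L) abort(sprintf("lexicon file is empty: %s", path))
  make_lexicon(lines, config)
}

make_lexicon <- function(lines, config) {
  normalized <- lapply(lines, normalize_term, config = config)
  n_tok <- lengths(normalized)
  dropped_multiword <- lines[n_tok > 1L]
  if (length(dropped_multiword) > 0L) {
    warn(sprintf(
      "%d multiword lexicon entr%s dropped (unigram analysis): %s",
      length(dropped_multiword),
      if (length(dropped_multiword) == 1L) "y" else "ies",
      paste(head(dropped_multiword, 5L), collapse = ", ")
    ))
  }
  entries <- sort(unique(unlist(normalized[n_tok == 1L], use.names = FALSE)),
                  method = "radix")
  if (length(entries) == 0L) {
    abort("lexicon has no usable single-token entries")
  }
  structure(list(entries = entries, dropped_multiword = dropped_multiword),
            class = "ctopic_lexicon")
}

#' Build a lexicon from an in-memory term vector
#'
#' Programmatic counterpart of [load_lexicon()], mainly for simulations and
#' tests.
#'
#' @param terms Character vector of raw candidate terms.
#' @param config A [preprocess_config()].
#' @return A `ctopic_lexicon`.
#' @export
lexicon <- function(terms, config = preprocess_config()) {
  stopifnot(is.character(terms), length(terms) > 0L)
  terms <- stringr::str_trim(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) abort("no lexicon terms supplied")
  make_lexicon(terms, config)
}

#' @export
print.ctopic_lexicon <- function(x, ...) {
  cat(sprintf(
    "<ctopic_lexicon> %d entr%s (%d multiword source line(s) dropped)\n",
    length(x$entries), if (length(x$entries) == 1L) "y" else "ies",
    length(x$dropped_multiword)
  ))
  invisible(x)
}

#' Selection thresholds configuration
#'
#' @param percentile Score percentile (strictly between 0 and 100) above
#'   which terms are kept; default 75.
#' @param min_proportion Strict lower bound on the proportional occurrence
#'   `b`; default 0.5.
#' @param require_lexicon Must selected terms belong to the lexicon?
#'   Default `TRUE`.
#' @return A `ctopic_selection_config` list.
#' @export
selection_config <- function(percentile = 75, min_proportion = 0.5,
                             require_lexicon = TRUE) {
  check_scalar_number(percentile, "percentile")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must lie strictly between 0 and 100")
  }
  check_scalar_number(min_proportion, "min_proportion", 0, 1)
  stopifnot(is.logical(require_lexicon), length(require_lexicon) == 1L)
  structure(
    list(percentile = percentile, min_proportion = min_proportion,
         require_lexicon = isTRUE(require_lexicon)),
    class = "ctopic_selection_config"
  )
}

#' Percentile threshold over a score distribution
#'
#' Linear-interpolation percentile (R's default quantile definition,
#' type 7) taken over the complete score distribution of the test set,
#' before any filtering.
#'
#' @param scores Numeric vector of scores (at least one).
#' @param percentile Percentile in (0, 100).
#' @return The threshold value.
#' @export
#' @examples
#' percentile_threshold(c(0, 0.25, 0.5, 0.75, 1), 75)
percentile_threshold <- function(scores, percentile = 75) {
  if (length(scores) == 0L || !is.numeric(scores)) {
    abort("`scores` must be a non-empty numeric vector")
  }
  check_scalar_number(percentile, "percentile", 0, 100)
  unname(quantile(scores, probs = percentile / 100, type = 7, names = FALSE))
}

#' Select potential determinant terms
#'
#' Applies the three filters to a scored term table: proportional
#' occurrence strictly above `min_proportion`, score strictly above the
#' `percentile` threshold of the full score distribution, and (by default)
#' membership in the lexicon. The filters commute; survivors are ranked by
#' score descending with alphabetical tie-break.
#'
#' @param stats Term statistics from [score_terms()] (the full test set).
#' @param lexicon A `ctopic_lexicon`, or `NULL` when
#'   `config$require_lexicon` is `FALSE`.
#' @param config A [selection_config()].
#' @return The selected rows of `stats`, ranked, with a `selected = TRUE`
#'   column; attributes `threshold` (the percentile threshold value) and
#'   `filter_counts` (named survivor counts per filter stage). An empty
#'   result is valid and reported with a message.
#' @export
select_determinants <- function(stats, lexicon = NULL,
                                config = selection_config()) {
  stopifnot(is.data.frame(stats), inherits(config, "ctopic_selection_config"))
  needed <- c("term", "b", "score")
  missing_cols <- setdiff(needed, names(stats))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`stats` is missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (config$require_lexicon) {
    if (!inherits(lexicon, "ctopic_lexicon")) {
      abort("a `ctopic_lexicon` is required when `require_lexicon = TRUE`")
    }
  }
  threshold <- percentile_threshold(stats$score, config$percentile)
  pass_b <- stats$b > config$min_proportion
  pass_score <- stats$score > threshold
  pass_lex <- if (config$require_lexicon) stats$term %in% lexicon$entries else TRUE
  keep <- pass_b & pass_score & pass_lex
  out <- stats[keep, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$score), .data$term) |>
    dplyr::mutate(selected = TRUE)
  if (nrow(out) == 0L) {
    inform("no terms survive the selection filters")
  }
  attr(out, "threshold") <- threshold
  attr(out, "filter_counts") <- c(
    test_set = nrow(stats),
    b_filter = sum(pass_b),
    score_filter = sum(pass_score),
    lexicon_filter = sum(pass_lex & TRUE),
    selected = nrow(out)
  )
  out
}
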