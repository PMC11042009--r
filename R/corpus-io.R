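# Reading document collections and writing result tables.

#' Construct a corpus from in-memory documents
#'
#' A corpus is a labelled, ordered collection of plain-text documents. Most
#' users will build one with [read_corpus()]; this constructor exists for
#' programmatic corpora (tests, simulations).
#'
#' @param docs Named character vector: names are document ids (unique,
#'   non-empty), values are raw document text.
#' @param label Corpus label, `"positive"` or `"negative"`.
#' @param allow_empty Permit documents whose text is empty? Default `FALSE`.
#'
#' @return An object of class `ctopic_corpus`: a tibble with columns
#'   `doc_id` and `text`, plus a `label` attribute.
#' @export
#' @examples
#' corpus(c(a = "zinc and copper", b = "copper only"), "positive")
corpus <- function(docs, label = c("positive", "negative"), allow_empty = FALSE) {
  label <- match.arg(label)
  if (length(docs) == 0L) {
    abort("no documents found: a corpus needs at least one document")
  }
  ids <- names(docs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    abort("every document must have a non-empty doc_id (names of `docs`)")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate doc_id within corpus: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (!allow_empty && any(!nzchar(docs))) {
    abort(sprintf(
      "empty document(s): %s (use allow_empty = TRUE to permit)",
      paste(ids[!nzchar(docs)], collapse = ", ")
    ))
  }
  out <- tibble::tibble(doc_id = unname(ids), text = unname(docs))
  structure(out, label = label, class = c("ctopic_corpus", class(out)))
}

#' Read a directory of plain-text files as a corpus
#'
#' One document per `.txt` file; the document id is the file name without
#' extension. Files are read as UTF-8 and rejected (with the offending file
#' named) if they do not decode. Document order is lexicographic in the file
#' name, so repeated loads of the same directory are byte-identical.
#'
#' @param directory Path to a directory containing at least one `.txt` file.
#' @param label `"positive"` or `"negative"`.
#' @param allow_empty Permit empty files? Default `FALSE`.
#'
#' @return A `ctopic_corpus` (see [corpus()]).
#' @export
read_corpus <- function(directory, label = c("positive", "negative"),
                        allow_empty = FALSE) {
  label <- match.arg(label)
  check_string(directory, "directory")
  if (!dir.exists(directory)) {
    abort(sprintf("corpus directory does not exist: %s", directory))
  }
  files <- list.files(directory, pattern = "\\.txt$", full.names = TRUE)
  files <- sort(files, method = "radix")  # locale-independent ordering
  if (length(files) == 0L) {
    abort(sprintf("no documents found in %s (expected *.txt files)", directory))
  }
  texts <- vapply(files, read_utf8_file, character(1))
  names(texts) <- tools::file_path_sans_ext(basename(files))
  corpus(texts, label = label, allow_empty = allow_empty)
}

read_utf8_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    abort(sprintf("file is not valid UTF-8: %s", path))
  }
  txt
}

#' @export
print.ctopic_corpus <- function(x, ...) {
  cat(sprintf(
    "<ctopic_corpus> label=%s, %d document(s)\n",
    attr(x, "label"), nrow(x)
  ))
  NextMethod()
}

#' Corpus label accessor
#' @param x A `ctopic_corpus`.
#' @return `"positive"` or `"negative"`.
#' @export
corpus_label <- function(x) {
  stopifnot(inherits(x, "ctopic_corpus"))
  attr(x, "label")
}

#' Pair a positive and a negative corpus
#'
#' The comparative method inherently requires two corpora: one of reports
#' with significant positive findings and one of insignificant/negative
#' findings on the same question. Document ids must be disjoint across the
#' pair; colliding ids are namespaced by the corpus label with a warning.
#'
#' @param positive,negative `ctopic_corpus` objects with matching labels.
#' @return An object of class `ctopic_corpus_pair` (a list with elements
#'   `positive` and `negative`).
#' @export
corpus_pair <- function(positive, negative) {
  stopifnot(inherits(positive, "ctopic_corpus"), inherits(negative, "ctopic_corpus"))
  if (!identical(corpus_label(positive), "positive")) {
    abort("`positive` must be a corpus with label \"positive\"")
  }
  if (!identical(corpus_label(negative), "negative")) {
    abort("`negative` must be a corpus with label \"negative\"")
  }
  shared <- intersect(positive$doc_id, negative$doc_id)
  if (length(shared) > 0L) {
    warn(sprintf(
      "doc_id collision across corpora (%s); namespacing by label",
      paste(shared, collapse = ", ")
    ))
    positive$doc_id <- paste0("positive/", positive$doc_id)
    negative$doc_id <- paste0("negative/", negative$doc_id)
  }
  structure(list(positive = positive, negative = negative),
            class = "ctopic_corpus_pair")
}

#' @export
print.ctopic_corpus_pair <- function(x, ...) {
  cat(sprintf(
    "<ctopic_corpus_pair> positive: %d doc(s), negative: %d doc(s)\n",
    nrow(x$positive), nrow(x$negative)
  ))
  invisible(x)
}

# Result serialization ---------------------------------------------------

results_columns <- c(
  "term", "n_pos", "n_total", "b",
  "doc_count_pos", "dist_fraction", "score", "selected"
)

#' Write a term-statistics table to TSV or JSON
#'
#' Columns: `term`, `n_pos`, `n_total`, `b`, `doc_count_pos`,
#' `dist_fraction`, `score`, `selected`. Ratio fields are serialized at four
#' decimal places; rows are sorted by score descending with ties broken
#' alphabetically, so output is byte-stable across runs.
#'
#' @param stats A term-statistics tibble from [score_terms()], optionally
#'   carrying a logical `selected` column (added as all-`FALSE` if missing).
#' @param path Output file path.
#' @param format `"tsv"` (tab-delimited with header) or `"json"`
#'   (array of records).
#' @param allow_empty Permit writing a table with zero rows? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_results <- function(stats, path, format = c("tsv", "json"),
                          allow_empty = FALSE) {
  format <- match.arg(format)
  check_string(path, "path")
  if (!is.data.frame(stats)) abort("`stats` must be a data frame of term statistics")
  if (nrow(stats) == 0L && !allow_empty) {
    abort("refusing to write an empty results table (set allow_empty = TRUE)")
  }
  if (!"selected" %in% names(stats)) stats$selected <- FALSE
  missing_cols <- setdiff(results_columns, names(stats))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`stats` is missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  out <- stats |>
    dplyr::arrange(dplyr::desc(.data$score), .data$term) |>
    dplyr::mutate(
      dplyr::across(c("b", "dist_fraction", "score"), ~ round(.x, 4))
    ) |>
    dplyr::select(dplyr::all_of(results_columns))
  if (format == "tsv") {
    fmt <- out |>
      dplyr::mutate(dplyr::across(c("b", "dist_fraction", "score"),
                                  ~ sprintf("%.4f", .x)))
    readr::write_tsv(fmt, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path File written by [write_results()].
#' @param format `"tsv"` or `"json"`; default guesses from the extension.
#' @return A tibble with the standard results columns.
#' @export
read_results <- function(path, format = NULL) {
  check_string(path, "path")
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    readr::read_tsv(
      path, progress = FALSE, show_col_types = FALSE,
      col_types = readr::cols(
        term = readr::col_character(),
        n_pos = readr::col_integer(),
        n_total = readr::col_integer(),
        b = readr::col_double(),
        doc_count_pos = readr::col_integer(),
        dist_fraction = readr::col_double(),
        score = readr::col_double(),
        selected = readr::col_logical()
      )
    )
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
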