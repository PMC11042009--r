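# End-to-end orchestration: load -> normalize -> score -> select ->
# write, with a run manifest capturing the aggregates a reader needs to
# desk-check a run (corpus word counts, test-set size, threshold, survivor
# counts per filter).

#' Run the full determinant-scoring pipeline
#'
#' @param pos_dir,neg_dir Directories of positive- and negative-corpus
#'   `.txt` documents.
#' @param lexicon_path Path to the candidate-term lexicon (one term per
#'   line), or `NULL` when `selection$require_lexicon` is `FALSE`.
#' @param config A [preprocess_config()].
#' @param selection A [selection_config()].
#' @param out_path Optional path for the results table
#'   ([write_results()]); format follows the extension (`.json` or TSV).
#' @param quiet Suppress progress messages? Default `FALSE`.
#' @return A list with `stats` (all scored terms), `selected` (ranked
#'   selection), and `manifest` (see details). The manifest records the
#'   configuration snapshot, raw corpus word counts, test-set size,
#'   percentile threshold, per-filter survivor counts, package version and
#'   timestamp.
#' @export
run_scoring_pipeline <- function(pos_dir, neg_dir, lexicon_path = NULL,
                                 config = preprocess_config(),
                                 selection = selection_config(),
                                 out_path = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  pair <- corpus_pair(
    read_corpus(pos_dir, "positive"),
    read_corpus(neg_dir, "negative")
  )
  lex <- NULL
  if (selection$require_lexicon) {
    if (is.null(lexicon_path)) {
      abort("a lexicon path is required when `require_lexicon = TRUE`")
    }
    lex <- load_lexicon(lexicon_path, config)
  }
  norm <- normalize_corpus(pair, config)
  wc_pos <- corpus_word_count(norm$positive)
  wc_neg <- corpus_word_count(norm$negative)
  say("positive corpus: %d document(s), %d raw words", length(norm$positive), wc_pos)
  say("negative corpus: %d document(s), %d raw words", length(norm$negative), wc_neg)
  if (min(wc_pos, wc_neg) > 0 &&
      abs(wc_pos - wc_neg) / max(wc_pos, wc_neg) > 0.25) {
    warn(sprintf(
      "corpus lengths differ by more than 25%% (%d vs %d words); proportional-occurrence values may need length-aware interpretation",
      wc_pos, wc_neg
    ))
  }
  stats <- score_terms(norm)
  say("test set: %d unique term(s)", nrow(stats))
  selected <- select_determinants(stats, lex, selection)
  threshold <- attr(selected, "threshold")
  filter_counts <- attr(selected, "filter_counts")
  say("score threshold (percentile %s): %.4f", selection$percentile, threshold)
  say("selected %d term(s)", nrow(selected))

  manifest <- list(
    config = list(
      lemmatizer = config$lemmatizer,
      n_stopwords = length(config$stopwords),
      keep_internal_hyphens = config$keep_internal_hyphens,
      strip_digits = config$strip_digits,
      percentile = selection$percentile,
      min_proportion = selection$min_proportion,
      require_lexicon = selection$require_lexicon
    ),
    word_count_pos = wc_pos,
    word_count_neg = wc_neg,
    n_docs_pos = length(norm$positive),
    n_docs_neg = length(norm$negative),
    n_test_set = nrow(stats),
    threshold = threshold,
    filter_counts = as.list(filter_counts),
    n_lexicon = if (is.null(lex)) NA_integer_ else length(lex$entries),
    tool_version = as.character(utils::packageVersion("ctopic")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_path)) {
    fmt <- if (grepl("\\.json$", out_path, ignore.case = TRUE)) "json" else "tsv"
    all_rows <- stats |>
      dplyr::mutate(selected = .data$term %in% selected$term)
    write_results(all_rows, out_path, format = fmt, allow_empty = TRUE)
    manifest_path <- paste0(tools::file_path_sans_ext(out_path), "_manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("results written to %s (manifest: %s)", out_path, manifest_path)
  }
  list(stats = stats, selected = selected, manifest = manifest)
}

#' Run the TF-IDF mean-ranking baseline over two corpus directories
#'
#' @param pos_dir,neg_dir Corpus directories.
#' @param terms Character vector of raw terms of interest (normalized
#'   before ranking).
#' @param config A [preprocess_config()].
#' @param out_path Optional TSV output (`term`, `mean_rank_pos`,
#'   `mean_rank_neg`, `NA` sentinel for corpus-absent terms).
#' @return The mean-rank tibble ([mean_rank_table()]).
#' @export
run_tfidf_baseline <- function(pos_dir, neg_dir, terms,
                               config = preprocess_config(),
                               out_path = NULL) {
  if (length(terms) == 0L || !is.character(terms)) {
    abort("at least one term of interest is required")
  }
  pair <- corpus_pair(
    read_corpus(pos_dir, "positive"),
    read_corpus(neg_dir, "negative")
  )
  norm <- normalize_corpus(pair, config)
  norm_terms <- unique(unlist(lapply(terms, normalize_term, config = config),
                              use.names = FALSE))
  if (length(norm_terms) == 0L) abort("no terms survive normalization")
  tab <- mean_rank_table(norm_terms, norm)
  if (!is.null(out_path)) {
    readr::write_tsv(tab, out_path, na = "NA", progress = FALSE)
  }
  tab
}
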