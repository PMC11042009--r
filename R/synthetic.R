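# Synthetic two-corpus generator: Zipfian background text over a shared
# vocabulary, with planted determinant terms whose proportional occurrence
# and positive-corpus document distribution are controlled. Plants are
# substituted into already-sampled background tokens, so document lengths
# are untouched and realized counts are exact by construction.

#' Describe a planted determinant term
#'
#' @param term The term to plant; must already be a normalized single token
#'   (it passes the normalization pipeline unchanged) and must not collide
#'   with the background vocabulary.
#' @param target_b Target proportional occurrence in \[0, 1\].
#' @param target_dist Target positive-corpus document distribution in
#'   \[0, 1\].
#' @param total_occurrences Total occurrences across both corpora.
#' @return A `ctopic_planted_term` list.
#' @export
planted_term <- function(term, target_b, target_dist, total_occurrences) {
  check_string(term, "term")
  check_scalar_number(target_b, "target_b", 0, 1)
  check_scalar_number(target_dist, "target_dist", 0, 1)
  check_scalar_number(total_occurrences, "total_occurrences", 1)
  structure(
    list(term = term, target_b = target_b, target_dist = target_dist,
         total_occurrences = as.integer(total_occurrences)),
    class = "ctopic_planted_term"
  )
}

#' Specification of a synthetic corpus pair
#'
#' Defaults emulate the scale of a two-corpus comparison of full-text study
#' reports: nine positive and seven negative documents of roughly 7,200
#' words each, drawn from a 20,000-term Zipfian background vocabulary.
#'
#' @param n_docs_pos,n_docs_neg Number of documents per corpus.
#' @param doc_length_mean Mean document length in tokens (Poisson).
#' @param vocab_size Background vocabulary size.
#' @param zipf_exponent Zipf rank exponent (> 0); token probability is
#'   proportional to `rank^-zipf_exponent`.
#' @param planted List of [planted_term()] objects.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `ctopic_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_docs_pos = 9, n_docs_neg = 7,
                           doc_length_mean = 7200, vocab_size = 20000,
                           zipf_exponent = 1.05, planted = list(),
                           seed = 1) {
  check_scalar_number(n_docs_pos, "n_docs_pos", 1)
  check_scalar_number(n_docs_neg, "n_docs_neg", 1)
  check_scalar_number(doc_length_mean, "doc_length_mean", 1)
  check_scalar_number(vocab_size, "vocab_size", 1)
  check_scalar_number(zipf_exponent, "zipf_exponent")
  if (zipf_exponent <= 0) abort("`zipf_exponent` must be positive")
  check_scalar_number(seed, "seed")
  if (inherits(planted, "ctopic_planted_term")) planted <- list(planted)
  stopifnot(is.list(planted))
  for (p in planted) {
    if (!inherits(p, "ctopic_planted_term")) {
      abort("`planted` must be a list of planted_term() objects")
    }
  }
  terms <- vapply(planted, function(p) p$term, character(1))
  if (anyDuplicated(terms)) abort("planted terms must be distinct")
  structure(
    list(n_docs_pos = as.integer(n_docs_pos),
         n_docs_neg = as.integer(n_docs_neg),
         doc_length_mean = doc_length_mean,
         vocab_size = as.integer(vocab_size),
         zipf_exponent = zipf_exponent,
         planted = planted,
         seed = as.integer(seed)),
    class = "ctopic_synthetic_spec"
  )
}

# Run code under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a plant against the spec before any sampling.
plant_allocation <- function(p, spec) {
  n_pos <- as.integer(round(p$target_b * p$total_occurrences))
  n_neg <- p$total_occurrences - n_pos
  n_docs_target <- as.integer(ceiling(p$target_dist * spec$n_docs_pos))
  if (n_pos == 0L && n_docs_target > 0L) {
    abort(sprintf(
      "infeasible plant '%s': target_dist > 0 but no positive-corpus occurrences after rounding",
      p$term
    ))
  }
  if (n_pos > 0L && n_docs_target == 0L) {
    abort(sprintf(
      "infeasible plant '%s': positive occurrences require target_dist > 0", p$term
    ))
  }
  if (n_pos < n_docs_target) {
    abort(sprintf(
      "infeasible plant '%s': %d positive occurrence(s) cannot cover %d document(s)",
      p$term, n_pos, n_docs_target
    ))
  }
  list(n_pos = n_pos, n_neg = n_neg, n_docs_target = n_docs_target)
}

#' Generate a synthetic corpus pair with planted determinants
#'
#' Background tokens are sampled per document from a Zipfian distribution
#' over a shared vocabulary (terms `bkg00001`, `bkg00002`, ...). Each
#' planted term's occurrences are then substituted for background tokens:
#' its positive-corpus occurrences are spread over
#' `ceiling(target_dist * n_docs_pos)` distinct positive documents (at
#' least one each), and the remainder goes to the negative corpus. The
#' ground truth records the realized statistics, which can differ from the
#' targets by integer rounding only.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `pair` (a `ctopic_corpus_pair` of raw text
#'   documents) and `truth` (tibble `term`, `n_pos`, `n_total`, `b`,
#'   `doc_count_pos`, `dist_fraction`, `score` of realized values).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "ctopic_synthetic_spec"))
  vocab <- sprintf("bkg%05d", seq_len(spec$vocab_size))
  plant_terms <- vapply(spec$planted, function(p) p$term, character(1))
  bad <- plant_terms[plant_terms %in% vocab]
  if (length(bad) > 0L) {
    abort(sprintf("planted term(s) collide with background vocabulary: %s",
                  paste(bad, collapse = ", ")))
  }
  for (t in plant_terms) {
    norm <- normalize_term(t)
    if (!identical(norm, t)) {
      abort(sprintf(
        "planted term '%s' is not normalization-stable (normalizes to: %s)",
        t, paste(norm, collapse = " ")
      ))
    }
  }
  allocs <- lapply(spec$planted, plant_allocation, spec = spec)

  with_seed(spec$seed, {
    probs <- seq_len(spec$vocab_size)^(-spec$zipf_exponent)
    probs <- probs / sum(probs)
    sample_doc <- function() {
      len <- max(1L, rpois(1L, spec$doc_length_mean))
      vocab[sample.int(spec$vocab_size, len, replace = TRUE, prob = probs)]
    }
    pos_tokens <- replicate(spec$n_docs_pos, sample_doc(), simplify = FALSE)
    neg_tokens <- replicate(spec$n_docs_neg, sample_doc(), simplify = FALSE)

    # positions still holding background tokens, per document
    pos_free <- lapply(pos_tokens, function(x) seq_along(x))
    neg_free <- lapply(neg_tokens, function(x) seq_along(x))

    substitute_into <- function(tokens, free, doc_idx, n_occ, term) {
      # place n_occ copies of term into the given documents, >=1 each
      counts <- integer(length(doc_idx))
      if (length(doc_idx) > 0L) {
        counts[] <- 1L
        extra <- n_occ - length(doc_idx)
        capacity <- lengths(free[doc_idx]) - counts
        while (extra > 0L) {
          open <- which(capacity > 0L)
          if (length(open) == 0L) {
            abort(sprintf(
              "infeasible plant '%s': documents too short for %d occurrence(s)",
              term, n_occ
            ))
          }
          pick <- open[sample.int(length(open), 1L)]
          counts[pick] <- counts[pick] + 1L
          capacity[pick] <- capacity[pick] - 1L
          extra <- extra - 1L
        }
      }
      for (k in seq_along(doc_idx)) {
        i <- doc_idx[k]
        if (counts[k] > length(free[[i]])) {
          abort(sprintf(
            "infeasible plant '%s': document %d too short", term, i
          ))
        }
        at <- free[[i]][sample.int(length(free[[i]]), counts[k])]
        tokens[[i]][at] <- term
        free[[i]] <- setdiff(free[[i]], at)
      }
      list(tokens = tokens, free = free)
    }

    truth_rows <- vector("list", length(spec$planted))
    for (j in seq_along(spec$planted)) {
      p <- spec$planted[[j]]
      a <- allocs[[j]]
      target_docs <- if (a$n_docs_target > 0L) {
        sort(sample.int(spec$n_docs_pos, a$n_docs_target))
      } else integer(0)
      res <- substitute_into(pos_tokens, pos_free, target_docs, a$n_pos, p$term)
      pos_tokens <- res$tokens; pos_free <- res$free
      if (a$n_neg > 0L) {
        # negative occurrences are unconstrained across negative documents
        neg_docs <- sort(unique(sample.int(spec$n_docs_neg,
                                           min(a$n_neg, spec$n_docs_neg))))
        res <- substitute_into(neg_tokens, neg_free, neg_docs, a$n_neg, p$term)
        neg_tokens <- res$tokens; neg_free <- res$free
      }
      b_real <- if (p$total_occurrences > 0) a$n_pos / p$total_occurrences else NA_real_
      dist_real <- a$n_docs_target / spec$n_docs_pos
      truth_rows[[j]] <- tibble::tibble(
        term = p$term,
        n_pos = a$n_pos,
        n_total = p$total_occurrences,
        b = b_real,
        doc_count_pos = a$n_docs_target,
        dist_fraction = dist_real,
        score = (b_real + dist_real) / 2
      )
    }

    make_corpus <- function(tokens, prefix, label) {
      texts <- vapply(tokens, paste, character(1), collapse = " ")
      names(texts) <- sprintf("%s%02d", prefix, seq_along(texts))
      corpus(texts, label = label)
    }
    pair <- corpus_pair(
      make_corpus(pos_tokens, "pos", "positive"),
      make_corpus(neg_tokens, "neg", "negative")
    )
    truth <- if (length(truth_rows) > 0L) {
      dplyr::bind_rows(truth_rows)
    } else {
      tibble::tibble(term = character(), n_pos = integer(), n_total = integer(),
                     b = numeric(), doc_count_pos = integer(),
                     dist_fraction = numeric(), score = numeric())
    }
    list(pair = pair, truth = truth)
  })
}

#' Write a generated pair to disk
#'
#' Writes the two corpora as directories of `.txt` files (one per
#' document) plus a JSON ground-truth manifest, in the layout expected by
#' [read_corpus()].
#'
#' @param generated Result of [generate_pair()].
#' @param out_dir Output directory (created if missing); gains
#'   subdirectories `positive/` and `negative/` and a `truth.json`.
#' @return `out_dir`, invisibly.
#' @export
write_pair <- function(generated, out_dir) {
  check_string(out_dir, "out_dir")
  stopifnot(is.list(generated), !is.null(generated$pair))
  for (side in c("positive", "negative")) {
    d <- file.path(out_dir, side)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    cps <- generated$pair[[side]]
    for (i in seq_len(nrow(cps))) {
      readr::write_file(cps$text[i], file.path(d, paste0(cps$doc_id[i], ".txt")))
    }
  }
  jsonlite::write_json(generated$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Recovery metrics of a selection against planted ground truth
#'
#' @param selected Ranked selection from [select_determinants()] (or a
#'   character vector of selected terms in rank order).
#' @param truth Ground-truth tibble from [generate_pair()].
#' @return A list with `precision` (`NA` when nothing was selected),
#'   `recall`, and `rank_of_first_plant` (`NA` when no plant was
#'   selected).
#' @export
recovery_report <- function(selected, truth) {
  sel_terms <- if (is.character(selected)) selected else selected$term
  planted <- truth$term
  if (length(planted) == 0L) abort("ground truth contains no planted terms")
  hits <- sel_terms %in% planted
  precision <- if (length(sel_terms) == 0L) NA_real_ else mean(hits)
  recall <- sum(planted %in% sel_terms) / length(planted)
  first <- which(hits)
  list(
    precision = precision,
    recall = recall,
    rank_of_first_plant = if (length(first) == 0L) NA_real_ else first[1]
  )
}
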