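#' The fixed feature inventory
#'
#' Every message is described by 25 named non-negative features:
#' five lexical-field scores (one per HRQoL dimension), eight sentiment
#' counts, five grammar counts (pronouns, first-person singular and plural
#' markers, negation constructions, bare "pas" tokens), four conjugation
#' counts (infinitives, present, past, past participles) and three
#' structure features (characters, tokens, sentences). The order is fixed
#' and is the tie-break order used by feature selection.
#'
#' @return Character vector of the 25 feature names, in canonical order.
#' @export
feature_inventory <- function() {
  c(paste0("lex_", qol_dimensions()),
    paste0("sent_", sentiment_categories()),
    "n_pronouns", "n_first_singular", "n_first_plural",
    "n_negations", "n_not_tokens",
    "n_infinitive", "n_present", "n_past", "n_past_participle",
    "n_chars", "n_tokens", "n_sentences")
}

# Leftmost-longest count of non-overlapping expression occurrences over a
# token sequence. Expressions are pre-tokenized lists of token vectors.
.count_expressions <- function(tokens, expr_tokens) {
  if (length(expr_tokens) == 0 || length(tokens) == 0) return(0L)
  lens <- lengths(expr_tokens)
  keep <- lens > 0
  expr_tokens <- expr_tokens[keep]; lens <- lens[keep]
  if (length(expr_tokens) == 0) return(0L)
  n <- length(tokens)
  count <- 0L
  i <- 1L
  while (i <= n) {
    best <- 0L
    for (e in seq_along(expr_tokens)) {
      k <- lens[e]
      if (k > best && i + k - 1 <= n &&
          identical(tokens[i:(i + k - 1)], expr_tokens[[e]])) {
        best <- k
      }
    }
    if (best > 0L) {
      count <- count + 1L
      i <- i + best
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Lexical-field score of a message for one lexicon
#'
#' Counts non-overlapping, token-boundary-anchored occurrences of the
#' lexicon's expressions in the text, with leftmost-longest resolution;
#' multi-word expressions match as contiguous token sequences.
#'
#' @param text a single normalized string.
#' @param lex a [lexicon].
#' @return Non-negative integer count.
#' @export
lexical_field_score <- function(text, lex) {
  tokens <- tokenize_text(text)$token
  expr_tokens <- lapply(unclass(lex), function(e) tokenize_text(e)$token)
  .count_expressions(tokens, expr_tokens)
}

#' Sentiment counts of a message
#'
#' One [lexical_field_score()] per sentiment category; categories are
#' counted independently, so a word listed in two categories contributes to
#' both.
#'
#' @param text a single normalized string.
#' @param lexicons a [lexicon_set] containing the eight sentiment lexicons.
#' @return Named integer vector over [sentiment_categories()].
#' @export
sentiment_counts <- function(text, lexicons) {
  miss <- setdiff(sentiment_categories(), names(lexicons))
  if (length(miss)) {
    stop("missing sentiment lexicon(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tokens <- tokenize_text(text)$token
  vapply(sentiment_categories(), function(cat) {
    expr_tokens <- lapply(unclass(lexicons[[cat]]),
                          function(e) tokenize_text(e)$token)
    .count_expressions(tokens, expr_tokens)
  }, integer(1))
}

#' Extract the feature matrix of a corpus
#'
#' Computes the full 25-feature description (see [feature_inventory()]) of
#' every message. Raw counts, not normalized; see [fit_normalization()].
#'
#' @param corpus a [qol_corpus] with normalized texts.
#' @param lexicons a complete [lexicon_set] (five dimensions + eight
#'   sentiment categories).
#' @param tagger morphology tagger, default [french_tagger()].
#' @return A data frame of class `qol_features`: column `message_id`
#'   followed by the 25 numeric feature columns, one row per message, in
#'   corpus order.
#' @export
extract_features <- function(corpus, lexicons, tagger = french_tagger()) {
  miss <- missing_lexicons(lexicons)
  if (length(miss)) {
    stop("incomplete lexicon set; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dims <- qol_dimensions(); cats <- sentiment_categories()
  pre_tok <- lapply(c(dims, cats), function(nm) {
    lapply(unclass(lexicons[[nm]]), function(e) tokenize_text(e)$token)
  })
  names(pre_tok) <- c(dims, cats)
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    text <- corpus$text[i]
    tokens <- tokenize_text(text)$token
    tags <- tag_morphology(tokens, tagger)
    lex_scores <- vapply(dims, function(d) {
      .count_expressions(tokens, pre_tok[[d]])
    }, integer(1))
    sent <- vapply(cats, function(cat) {
      .count_expressions(tokens, pre_tok[[cat]])
    }, integer(1))
    c(stats::setNames(lex_scores, paste0("lex_", dims)),
      stats::setNames(sent, paste0("sent_", cats)),
      n_pronouns = sum(tags$pos == "pronoun"),
      n_first_singular = sum(tags$person == "1sg"),
      n_first_plural = sum(tags$person == "1pl"),
      n_negations = negation_count(tokens),
      n_not_tokens = not_count(tokens),
      n_infinitive = sum(tags$form == "infinitive"),
      n_present = sum(tags$tense == "present"),
      n_past = sum(tags$tense == "past"),
      n_past_participle = sum(tags$form == "past_participle"),
      n_chars = nchar(text),
      n_tokens = length(tokens),
      n_sentences = length(split_sentences(text)))
  })
  mat <- do.call(rbind, rows)
  out <- data.frame(message_id = corpus$id, mat, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out <- out[, c("message_id", feature_inventory())]
  rownames(out) <- NULL
  class(out) <- c("qol_features", "data.frame")
  out
}

#' Fit the feature normalization state on training data
#'
#' Records, per feature, the training median (used to impute missing
#' values) and the training maximum (used to scale all values into
#' \[0, 1\]). Fitted on training rows only, then applied unchanged to any
#' other data.
#'
#' @param features a `qol_features` data frame (training rows only).
#' @return An object of class `qol_normalization` with fields `max`,
#'   `median` (named numeric vectors) and `fitted_on`.
#' @export
fit_normalization <- function(features) {
  cols <- setdiff(names(features), "message_id")
  if (nrow(features) == 0) stop("empty feature matrix", call. = FALSE)
  maxima <- vapply(cols, function(cl) {
    v <- features[[cl]]
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  }, numeric(1))
  medians <- vapply(cols, function(cl) {
    v <- features[[cl]]
    if (all(is.na(v))) 0 else stats::median(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(max = maxima, median = medians,
                 fitted_on = sprintf("%d rows", nrow(features))),
            class = "qol_normalization")
}

#' Apply a fitted normalization to a feature matrix
#'
#' Per feature: impute missing values with the stored training median, then
#' divide by the stored training maximum (features whose training maximum
#' was 0 map to 0). Values on unseen data may exceed the training maximum
#' and are clipped to \[0, 1\].
#'
#' @param features a `qol_features` data frame.
#' @param state a `qol_normalization` from [fit_normalization()].
#' @return The normalized feature data frame (same shape).
#' @export
apply_normalization <- function(features, state) {
  stopifnot(inherits(state, "qol_normalization"))
  out <- features
  for (cl in names(state$max)) {
    if (!cl %in% names(out)) {
      stop("feature `", cl, "` absent from the matrix", call. = FALSE)
    }
    v <- out[[cl]]
    v[is.na(v)] <- state$median[[cl]]
    mx <- state$max[[cl]]
    v <- if (mx > 0) v / mx else rep(0, length(v))
    out[[cl]] <- pmin(pmax(v, 0), 1)
  }
  out
}

#' Serialize a normalization state to JSON
#'
#' @param state a `qol_normalization`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_normalization <- function(state, path) {
  obj <- lapply(names(state$max), function(nm) {
    list(max = state$max[[nm]], median = state$median[[nm]])
  })
  names(obj) <- names(state$max)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normalization state from JSON
#'
#' @param path JSON path written by [write_normalization()].
#' @return A `qol_normalization`.
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(max = vapply(obj, function(o) o$max, numeric(1)),
                 median = vapply(obj, function(o) o$median, numeric(1)),
                 fitted_on = "deserialized"),
            class = "qol_normalization")
}
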