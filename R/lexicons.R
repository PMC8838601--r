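#' The five HRQoL impact dimensions
#'
#' Physical, psychic, activity-related, relational and financial — the
#' dimensions along which a quality-of-life impact is attributed, inspired
#' by the EQ-5D / SF-36 questionnaire domains.
#'
#' @return Character vector of the five dimension names.
#' @export
qol_dimensions <- function() {
  c("physical", "psychic", "activity", "relational", "financial")
}

#' The eight sentiment categories
#'
#' @return Character vector of sentiment category names.
#' @export
sentiment_categories <- function() {
  c("positive", "negative", "anger", "disgust", "fear", "joy",
    "sadness", "surprise")
}

#' Construct a lexicon
#'
#' A lexicon is a named set of (possibly multi-word) expressions driving
#' one lexical-field or sentiment feature. Expressions are normalized with
#' [normalize_text()]; duplicates are collapsed; empty expressions are
#' rejected.
#'
#' @param name lexicon name (a dimension, a sentiment category, or any
#'   user-chosen name).
#' @param expressions character vector of expressions.
#' @param language language tag, default `"fr"`.
#' @return A character vector of class `qol_lexicon` with attributes
#'   `name` and `language`.
#' @export
lexicon <- function(name, expressions, language = "fr") {
  expressions <- normalize_text(as.character(expressions))
  if (any(!nzchar(expressions))) {
    stop("lexicon \"", name, "\" contains an empty expression", call. = FALSE)
  }
  expressions <- unique(expressions)
  structure(expressions, name = name, language = language,
            class = "qol_lexicon")
}

#' @export
print.qol_lexicon <- function(x, ...) {
  cat(sprintf("<qol_lexicon> %s (%d expressions)\n", attr(x, "name"),
              length(x)))
  invisible(x)
}

#' Bundle lexicons into a set
#'
#' A complete set carries the five dimension lexicons and the eight
#' sentiment lexicons; extra lexicons are allowed and kept under their
#' given names.
#'
#' @param ... [lexicon] objects, or a single named list of them.
#' @param version free-text version tag.
#' @return A named list of class `qol_lexicon_set`.
#' @export
lexicon_set <- function(..., version = "0") {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) &&
      !inherits(lst[[1]], "qol_lexicon")) {
    lst <- lst[[1]]
  }
  nms <- vapply(lst, function(l) attr(l, "name"), character(1))
  names(lst) <- nms
  structure(lst, version = version, class = "qol_lexicon_set")
}

#' Check a lexicon set for completeness
#'
#' @param lexicons a [lexicon_set].
#' @return Character vector of missing lexicon names (empty when complete).
#' @export
missing_lexicons <- function(lexicons) {
  setdiff(c(qol_dimensions(), sentiment_categories()), names(lexicons))
}

#' @export
print.qol_lexicon_set <- function(x, ...) {
  cat(sprintf("<qol_lexicon_set> %d lexicons (version %s)\n", length(x),
              attr(x, "version")))
  for (nm in names(x)) cat(sprintf("  %-12s %d expressions\n", nm,
                                   length(x[[nm]])))
  miss <- missing_lexicons(x)
  if (length(miss)) cat("  missing for a complete set:",
                        paste(miss, collapse = ", "), "\n")
  invisible(x)
}

#' Read lexicons from a JSON file
#'
#' The file is a JSON object mapping lexicon names to arrays of
#' expressions. Unknown names are kept (with a warning) under their given
#' name.
#'
#' @param path JSON path.
#' @return A [lexicon_set].
#' @export
read_lexicons <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed lexicon JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw) || is.null(names(raw))) {
    stop("lexicon file must be a JSON object of name -> expression arrays",
         call. = FALSE)
  }
  known <- c(qol_dimensions(), sentiment_categories())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("unknown lexicon name(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  lexicon_set(lapply(names(raw), function(nm) lexicon(nm, raw[[nm]])))
}

#' Write a lexicon set to JSON
#'
#' @param lexicons a [lexicon_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicons <- function(lexicons, path) {
  obj <- lapply(lexicons, function(l) as.character(unclass(l)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Build a dimension lexicon from captured annotation expressions
#'
#' During annotation, the expressions by which patients voice an impact are
#' captured as character spans. This collects the normalized expressions
#' tagged with one dimension across all annotators and keeps those occurring
#' at least `min_count` times.
#'
#' @param expressions a data frame of captured spans with columns
#'   `message_id`, `start`, `end`, `dimension` (offsets into normalized
#'   message text, 0-based half-open).
#' @param corpus the [qol_corpus] the spans refer to.
#' @param dimension the dimension to collect.
#' @param min_count minimum number of occurrences for an expression to be
#'   retained (default 1).
#' @return A [lexicon] for the dimension (possibly empty).
#' @export
build_lexicon_from_annotations <- function(expressions, corpus, dimension,
                                           min_count = 1L) {
  rows <- expressions[expressions$dimension == dimension, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(structure(character(0), name = dimension, language = "fr",
                     class = "qol_lexicon"))
  }
  text_by_id <- stats::setNames(corpus$text, corpus$id)
  surfaces <- vapply(seq_len(nrow(rows)), function(i) {
    txt <- text_by_id[[rows$message_id[i]]]
    if (is.null(txt)) return(NA_character_)
    substr(txt, rows$start[i] + 1, rows$end[i])
  }, character(1))
  surfaces <- normalize_text(surfaces[!is.na(surfaces)])
  counts <- table(surfaces)
  kept <- sort(names(counts)[counts >= min_count])
  if (length(kept) == 0) {
    return(structure(character(0), name = dimension, language = "fr",
                     class = "qol_lexicon"))
  }
  lexicon(dimension, kept)
}
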