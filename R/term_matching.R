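#' Construct a drug/disease term dictionary
#'
#' @param surface character vector of term surfaces; normalized with
#'   [normalize_text()] on construction.
#' @param canonical character vector of canonical names (defaults to the
#'   surfaces).
#' @param category `"drug"` or `"disease"` per entry.
#' @param name dictionary name.
#' @param match_mode `"exact"` or `"approximate"`; in exact mode every
#'   match has edit distance 0.
#' @return An object of class `qol_term_dictionary`: a data frame with
#'   columns `surface`, `canonical`, `category`.
#' @export
term_dictionary <- function(surface, canonical = surface,
                            category = "disease",
                            name = "dictionary",
                            match_mode = c("exact", "approximate")) {
  match_mode <- match.arg(match_mode)
  surface <- normalize_text(surface)
  if (length(surface) == 0 || !any(nzchar(surface))) {
    stop("a term dictionary needs at least one entry", call. = FALSE)
  }
  category <- rep_len(as.character(category), length(surface))
  if (!all(category %in% c("drug", "disease"))) {
    stop("`category` entries must be \"drug\" or \"disease\"", call. = FALSE)
  }
  df <- data.frame(surface = surface,
                   canonical = as.character(rep_len(canonical, length(surface))),
                   category = category, stringsAsFactors = FALSE)
  df <- df[nzchar(df$surface), , drop = FALSE]
  df <- df[!duplicated(df$surface), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, match_mode = match_mode,
            class = c("qol_term_dictionary", "data.frame"))
}

#' Read a term dictionary from CSV
#'
#' Expects columns `surface`, `canonical`, `category`.
#'
#' @param path CSV path.
#' @param name dictionary name (defaults to the file stem).
#' @param match_mode `"exact"` or `"approximate"`.
#' @return A [term_dictionary].
#' @export
read_term_dictionary <- function(path, name = NULL,
                                 match_mode = c("exact", "approximate")) {
  match_mode <- match.arg(match_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("surface", "category") %in% names(df))) {
    stop("dictionary CSV must have columns surface, category", call. = FALSE)
  }
  if (is.null(df$canonical)) df$canonical <- df$surface
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  term_dictionary(df$surface, df$canonical, df$category,
                  name = name, match_mode = match_mode)
}

# Maximum edit distance allowed for a surface, scaled by its length:
# short names admit no error, medium one, long two.
.allowed_distance <- function(surface_nchar, max_distance) {
  ifelse(surface_nchar < 5, 0L,
         ifelse(surface_nchar < 10, pmin(max_distance, 1L),
                pmin(max_distance, 2L)))
}

#' Find dictionary term mentions in a message
#'
#' Token-boundary-anchored matching: a dictionary surface of k tokens is
#' compared against every window of k consecutive message tokens; the window
#' matches when the Levenshtein distance between the joined window and the
#' surface is within the allowed budget. The budget scales with surface
#' length: 0 for surfaces under 5 characters, up to 1 for 5-9 characters,
#' up to 2 for 10 or more (always capped by `max_distance`, and forced to 0
#' when the dictionary is in exact mode). Overlapping candidates are
#' resolved leftmost-longest, then lowest distance.
#'
#' @param text a single normalized string.
#' @param dictionary a [term_dictionary].
#' @param max_distance non-negative integer cap on the edit distance.
#' @return A data frame of mentions, in span order: `start`, `end` (0-based,
#'   half-open character offsets), `surface` (matched substring),
#'   `canonical`, `category`, `edit_distance`.
#' @export
match_terms <- function(text, dictionary, max_distance = 1L) {
  stopifnot(max_distance >= 0)
  if (identical(attr(dictionary, "match_mode"), "exact")) max_distance <- 0L
  toks <- tokenize_text(text)
  empty <- data.frame(start = integer(0), end = integer(0),
                      surface = character(0), canonical = character(0),
                      category = character(0), edit_distance = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(toks) == 0) return(empty)
  surf_tokens <- lapply(dictionary$surface, function(s) tokenize_text(s)$token)
  surf_join <- vapply(surf_tokens, paste, character(1), collapse = " ")
  allowed <- .allowed_distance(nchar(dictionary$surface), max_distance)
  n <- nrow(toks)
  cand <- list()
  for (d in seq_len(nrow(dictionary))) {
    k <- length(surf_tokens[[d]])
    if (k == 0 || k > n) next
    for (i in seq_len(n - k + 1)) {
      window <- paste(toks$token[i:(i + k - 1)], collapse = " ")
      if (abs(nchar(window) - nchar(surf_join[d])) > allowed[d]) next
      dist <- utils::adist(window, surf_join[d])[1, 1]
      if (dist <= allowed[d]) {
        cand[[length(cand) + 1]] <- data.frame(
          start = toks$start[i], end = toks$end[i + k - 1],
          surface = substr(text, toks$start[i] + 1, toks$end[i + k - 1]),
          canonical = dictionary$canonical[d],
          category = dictionary$category[d],
          edit_distance = as.integer(dist),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  # leftmost-longest, then lowest distance, greedy non-overlap resolution
  cand <- cand[order(cand$start, -cand$end, cand$edit_distance), , drop = FALSE]
  chosen <- logical(nrow(cand))
  occupied_until <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= occupied_until) {
      chosen[i] <- TRUE
      occupied_until <- cand$end[i]
    }
  }
  out <- cand[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the health-related messages of a corpus
#'
#' A message is health-related when it contains at least one dictionary term
#' mention. Original corpus order is preserved.
#'
#' @param corpus a [qol_corpus] with normalized texts.
#' @param dictionary a [term_dictionary].
#' @param max_distance edit-distance cap passed to [match_terms()].
#' @return A list with elements `corpus` (the health-related sub-corpus) and
#'   `mentions` (the full mention table with a leading `message_id` column).
#' @export
filter_health_related <- function(corpus, dictionary, max_distance = 1L) {
  if (nrow(dictionary) == 0) stop("empty dictionary", call. = FALSE)
  mention_list <- lapply(seq_len(nrow(corpus)), function(i) {
    m <- match_terms(corpus$text[i], dictionary, max_distance)
    if (nrow(m) > 0) cbind(message_id = corpus$id[i], m,
                           stringsAsFactors = FALSE) else NULL
  })
  mentions <- do.call(rbind, mention_list)
  if (is.null(mentions)) {
    mentions <- data.frame(message_id = character(0), start = integer(0),
                           end = integer(0), surface = character(0),
                           canonical = character(0), category = character(0),
                           edit_distance = integer(0), stringsAsFactors = FALSE)
  }
  rownames(mentions) <- NULL
  keep <- corpus$id %in% mentions$message_id
  sub <- corpus[keep, , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- class(corpus)
  attr(sub, "provenance") <- attr(corpus, "provenance")
  list(corpus = sub, mentions = mentions)
}
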