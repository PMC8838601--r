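#' Construct a message corpus
#'
#' A corpus is an ordered collection of forum messages, one row per message,
#' with a stable iteration order (input order) and unique message ids.
#'
#' @param id character vector of unique message identifiers.
#' @param text character vector of message texts (raw or normalized).
#' @param source character vector (recycled) naming the forum of origin, or
#'   `"synthetic"` for generated messages.
#' @param posted_at optional character vector of ISO-8601 timestamps (`NA`
#'   allowed).
#' @param language BCP-47-ish language tag, default `"fr"`.
#' @param provenance free-text description of where the corpus came from.
#' @return An object of class `qol_corpus`: a data frame with columns
#'   `id`, `text`, `source`, `posted_at`, `language` and a `provenance`
#'   attribute.
#' @export
qol_corpus <- function(id, text, source = "unknown", posted_at = NA_character_,
                       language = "fr", provenance = "") {
  id <- as.character(id)
  text <- as.character(text)
  if (length(id) != length(text)) {
    stop("`id` and `text` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate message ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    id = id,
    text = text,
    source = rep_len(as.character(source), length(id)),
    posted_at = rep_len(as.character(posted_at), length(id)),
    language = rep_len(as.character(language), length(id)),
    stringsAsFactors = FALSE
  )
  structure(df, provenance = provenance,
            class = c("qol_corpus", "data.frame"))
}

#' @export
print.qol_corpus <- function(x, ...) {
  cat(sprintf("<qol_corpus> %d messages", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(" | ", prov, sep = "")
  cat("\n")
  if (nrow(x) > 0) {
    shown <- utils::head(x, 3)
    for (i in seq_len(nrow(shown))) {
      txt <- shown$text[i]
      if (nchar(txt) > 60) txt <- paste0(substr(txt, 1, 57), "...")
      cat(sprintf("  [%s] %s\n", shown$id[i], txt))
    }
    if (nrow(x) > 3) cat(sprintf("  ... and %d more\n", nrow(x) - 3))
  }
  invisible(x)
}

#' Read a message corpus from JSONL or CSV
#'
#' Records lacking an `id` receive a deterministic generated identifier
#' (the file stem followed by a zero-padded ordinal). Records whose `text`
#' is empty or whitespace-only are dropped; the number of dropped records is
#' kept in the `n_dropped` attribute of the result.
#'
#' @param path path to the corpus file.
#' @param format `"jsonl"` (one JSON object per line with keys `id`, `text`,
#'   optionally `source`, `posted_at`, `language`) or `"csv"` (header row,
#'   UTF-8, quoted text). Defaults to the file extension.
#' @return A [qol_corpus] with attributes `n_dropped` (count of empty-text
#'   records removed) and `provenance` (the source path).
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv")) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed JSON on line ", i,
                                               " of ", path, call. = FALSE))
      if (is.null(rec$text)) {
        stop("record ", i, " of ", path, " lacks a `text` field",
             call. = FALSE)
      }
      rec
    })
    get_field <- function(name, default) {
      vapply(recs, function(r) {
        v <- r[[name]]
        if (is.null(v) || length(v) == 0) default else as.character(v)[1]
      }, character(1))
    }
    id <- get_field("id", NA_character_)
    text <- get_field("text", NA_character_)
    source <- get_field("source", "unknown")
    posted_at <- get_field("posted_at", NA_character_)
    language <- get_field("language", "fr")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          encoding = "UTF-8", colClasses = "character")
    if (!"text" %in% names(df)) {
      stop("corpus CSV ", path, " lacks a `text` column", call. = FALSE)
    }
    id <- if ("id" %in% names(df)) df$id else rep(NA_character_, nrow(df))
    text <- df$text
    source <- if ("source" %in% names(df)) df$source else "unknown"
    posted_at <- if ("posted_at" %in% names(df)) df$posted_at else NA_character_
    language <- if ("language" %in% names(df)) df$language else "fr"
  }
  stem <- tools::file_path_sans_ext(basename(path))
  missing_id <- is.na(id) | !nzchar(id)
  if (any(missing_id)) {
    id[missing_id] <- sprintf("%s-%06d", stem, which(missing_id))
  }
  keep <- !is.na(text) & nzchar(trimws(text))
  n_dropped <- sum(!keep)
  corp <- qol_corpus(id[keep], text[keep],
                     source = if (length(source) > 1) source[keep] else source,
                     posted_at = if (length(posted_at) > 1) posted_at[keep] else posted_at,
                     language = if (length(language) > 1) language[keep] else language,
                     provenance = path)
  attr(corp, "n_dropped") <- n_dropped
  corp
}

#' Write a corpus to JSONL or CSV
#'
#' @param corpus a [qol_corpus].
#' @param path output path.
#' @param format `"jsonl"` or `"csv"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv")) "csv" else "jsonl"
  }
  df <- as.data.frame(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, c("id", "text", "source", "posted_at", "language")])
      rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

# Common HTML entities seen in crawled forum text; numeric entities are
# decoded separately.
.html_entities <- c(
  "&amp;" = "&", "&lt;" = "<", "&gt;" = ">", "&quot;" = "\"",
  "&apos;" = "'", "&nbsp;" = " ", "&eacute;" = "é",
  "&egrave;" = "è", "&agrave;" = "à", "&ccedil;" = "ç",
  "&ecirc;" = "ê", "&ocirc;" = "ô", "&ucirc;" = "û",
  "&icirc;" = "î", "&euml;" = "ë", "&iuml;" = "ï",
  "&ugrave;" = "ù", "&hellip;" = "…", "&rsquo;" = "'",
  "&#39;" = "'"
)

#' Normalize message text
#'
#' Applies the canonical normalization used everywhere in the pipeline:
#' Unicode NFC form, lowercasing (locale-independent), HTML entity decoding,
#' URL replacement by the token `<url>`, collapsing of whitespace runs to
#' single spaces, and stripping of leading/trailing whitespace. Accents are
#' preserved. The function is total and idempotent; all character offsets in
#' the pipeline (mention and expression spans) refer to normalized text,
#' 0-based, half-open.
#'
#' @param raw character vector of raw texts.
#' @return character vector of normalized texts.
#' @export
normalize_text <- function(raw) {
  x <- stringi::stri_trans_nfc(enc2utf8(as.character(raw)))
  # named entities, then decimal and hex numeric entities
  for (ent in names(.html_entities)) {
    x <- gsub(ent, .html_entities[[ent]], x, fixed = TRUE)
  }
  x <- vapply(x, function(s) {
    m <- gregexpr("&#x?[0-9a-fA-F]+;", s)[[1]]
    if (m[1] == -1) return(s)
    parts <- regmatches(s, gregexpr("&#x?[0-9a-fA-F]+;", s))[[1]]
    for (p in unique(parts)) {
      code <- sub("&#x?", "", sub(";", "", p))
      base <- if (grepl("x", p, fixed = TRUE)) 16L else 10L
      ch <- intToUtf8(strtoi(code, base))
      s <- gsub(p, ch, s, fixed = TRUE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
  x <- stringi::stri_replace_all_regex(x, "(?i)(?:https?://|www\\.)\\S+", "<url>")
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Remove duplicate messages from a corpus
#'
#' Messages whose (already normalized) text is byte-identical to an earlier
#' message are removed; the first occurrence is kept. The number of removed
#' messages is stored in the `n_removed` attribute.
#'
#' @param corpus a [qol_corpus] with normalized texts.
#' @return The deduplicated [qol_corpus].
#' @export
deduplicate_corpus <- function(corpus) {
  keep <- !duplicated(corpus$text)
  out <- corpus[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(corpus, "provenance")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(corpus)
  out
}

# Abbreviations that end in "." but do not terminate a sentence.
.default_abbreviations <- c(
  "dr.", "mr.", "mme.", "mlle.", "prof.", "etc.", "ex.", "cf.", "env.",
  "tel.", "av.", "bd.", "st.", "ste."
)

#' Split normalized text into sentences
#'
#' Rule-based splitter: boundaries occur at `.`, `!`, `?` or ellipsis
#' followed by whitespace and a letter, except when the terminator belongs
#' to a known abbreviation. The concatenation of the sentences, joined by
#' single spaces, reconstructs the text (minus boundary whitespace).
#'
#' @param text a single normalized string.
#' @param abbreviations character vector of abbreviation stop-words (ending
#'   in `.`) that never terminate a sentence.
#' @return Character vector of sentences, in order.
#' @export
split_sentences <- function(text, abbreviations = .default_abbreviations) {
  stopifnot(length(text) == 1)
  if (!nzchar(text)) return(character(0))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  boundaries <- integer(0)
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?", "…")) {
      # absorb a run of terminators ("!!", "...")
      j <- i
      while (j < n && chars[j + 1] %in% c(".", "!", "?", "…")) j <- j + 1
      followed <- j < n && chars[j + 1] == " " &&
        (j + 1) < n && grepl("[[:alpha:]]", chars[j + 2])
      is_abbrev <- FALSE
      if (ch == "." && i == j) {
        # token ending at i: read back to previous space
        k <- i
        while (k > 1 && chars[k - 1] != " ") k <- k - 1
        token <- paste(chars[k:i], collapse = "")
        is_abbrev <- token %in% abbreviations
      }
      if (followed && !is_abbrev) boundaries <- c(boundaries, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  starts <- c(1, boundaries + 2)  # skip the single space after each boundary
  ends <- c(boundaries, n)
  out <- vapply(seq_along(starts), function(s) {
    paste(chars[starts[s]:ends[s]], collapse = "")
  }, character(1))
  trimws(out)
}

#' Split a corpus into training and validation sets
#'
#' Uniform random partition: `floor(ratio * n)` messages go to the training
#' set, the remainder to validation. Deterministic given the corpus order,
#' the ratio and the seed. A 1399-message corpus at ratio 0.70 yields
#' 979 training and 420 validation messages.
#'
#' @param corpus a [qol_corpus].
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed for the partition.
#' @param stratify_by optional logical vector (length `nrow(corpus)`) to
#'   stratify on, e.g. the impact label; default unstratified.
#' @return A list of class `qol_split` with elements `train` and
#'   `validation` (both [qol_corpus]), `ratio` and `seed`.
#' @export
split_corpus <- function(corpus, ratio = 0.7, seed = 1L, stratify_by = NULL) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must be a single number in (0, 1)", call. = FALSE)
  }
  n <- nrow(corpus)
  if (n == 0) stop("corpus is empty", call. = FALSE)
  n_train <- floor(ratio * n)
  idx <- local({
    set.seed(as.integer(seed))
    if (is.null(stratify_by)) {
      sample.int(n, n_train)
    } else {
      stopifnot(length(stratify_by) == n)
      picked <- integer(0)
      for (lev in unique(stratify_by)) {
        members <- which(stratify_by == lev)
        k <- round(length(members) * ratio)
        picked <- c(picked, sample(members, min(k, length(members))))
      }
      # adjust to the exact floor(ratio * n) size deterministically
      if (length(picked) > n_train) {
        picked <- picked[seq_len(n_train)]
      } else if (length(picked) < n_train) {
        pool <- setdiff(seq_len(n), picked)
        picked <- c(picked, sample(pool, n_train - length(picked)))
      }
      picked
    }
  })
  idx <- sort(idx)
  take <- function(rows) {
    out <- corpus[rows, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(corpus)
    out
  }
  structure(list(train = take(idx),
                 validation = take(setdiff(seq_len(n), idx)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "qol_split")
}

#' @export
print.qol_split <- function(x, ...) {
  cat(sprintf("<qol_split> ratio %.2f, seed %d: %d train / %d validation\n",
              x$ratio, x$seed, nrow(x$train), nrow(x$validation)))
  invisible(x)
}
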