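#' Tokenize normalized text
#'
#' Splits normalized text into word tokens with character offsets. Tokens
#' are maximal runs of letters, digits and apostrophes; elided French
#' clitics are split after the apostrophe, so `"j'ai"` yields the tokens
#' `"j'"` and `"ai"`. Offsets are 0-based, half-open, into the input string.
#'
#' @param text a single normalized string.
#' @return A data frame with columns `token`, `start`, `end`.
#' @export
tokenize_text <- function(text) {
  stopifnot(length(text) == 1)
  empty <- data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  loc <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}'’]+")[[1]]
  if (is.na(loc[1, 1])) return(empty)
  tokens <- character(0); starts <- integer(0); ends <- integer(0)
  for (r in seq_len(nrow(loc))) {
    a <- loc[r, 1]; b <- loc[r, 2]
    run <- substr(text, a, b)
    # drop runs that are only apostrophes
    if (!grepl("[\\p{L}\\p{N}]", run, perl = TRUE)) next
    # split after each apostrophe: "j'ai" -> "j'", "ai"
    pieces <- strsplit(run, "(?<=['’])", perl = TRUE)[[1]]
    pos <- a
    for (p in pieces) {
      if (grepl("[\\p{L}\\p{N}]", p, perl = TRUE)) {
        tokens <- c(tokens, p)
        starts <- c(starts, pos)
        ends <- c(ends, pos + nchar(p))
      }
      pos <- pos + nchar(p)
    }
  }
  data.frame(token = tokens, start = starts - 1L, end = ends - 1L,
             stringsAsFactors = FALSE)
}
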