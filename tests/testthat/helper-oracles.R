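# Independent brute-force oracles and tiny in-code fixtures shared by the
# tests. The oracles deliberately use naive enumeration, not the package's
# own algorithms.

# AUC by exhaustive pair counting, ties worth 1/2.
brute_auc <- function(y, scores) {
  pos <- scores[as.logical(y)]
  neg <- scores[!as.logical(y)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Cohen's kappa from the hand-tabulated 2x2 contingency table.
brute_kappa <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  n <- length(a)
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- sum(!a & !b)
  po <- (n11 + n00) / n
  pe <- ((n11 + n10) / n) * ((n11 + n01) / n) +
    ((n01 + n00) / n) * ((n10 + n00) / n)
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# Every-window-vs-every-surface scan with the length-scaled distance
# ladder, resolved leftmost-longest then lowest distance by repeated
# selection from the candidate table.
brute_match_terms <- function(text, dictionary, max_distance) {
  if (identical(attr(dictionary, "match_mode"), "exact")) max_distance <- 0L
  toks <- tokenize_text(text)
  cands <- list()
  for (d in seq_len(nrow(dictionary))) {
    surf <- dictionary$surface[d]
    stoks <- tokenize_text(surf)$token
    nc <- nchar(surf)
    allowed <- if (nc < 5) 0 else if (nc < 10) min(max_distance, 1) else
      min(max_distance, 2)
    k <- length(stoks)
    if (k == 0 || k > nrow(toks)) next
    for (i in seq_len(nrow(toks) - k + 1)) {
      window <- paste(toks$token[i:(i + k - 1)], collapse = " ")
      dist <- utils::adist(window, paste(stoks, collapse = " "))[1, 1]
      if (dist <= allowed) {
        cands[[length(cands) + 1]] <- data.frame(
          start = toks$start[i], end = toks$end[i + k - 1],
          canonical = dictionary$canonical[d],
          edit_distance = dist, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(0), end = integer(0),
                      canonical = character(0), edit_distance = integer(0)))
  }
  tab <- do.call(rbind, cands)
  picked <- list()
  repeat {
    if (nrow(tab) == 0) break
    best <- tab[tab$start == min(tab$start), , drop = FALSE]
    best <- best[best$end == max(best$end), , drop = FALSE]
    best <- best[which.min(best$edit_distance), , drop = FALSE]
    picked[[length(picked) + 1]] <- best
    tab <- tab[tab$start >= best$end, , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

# Exhaustive leftmost-longest expression counter over token sequences.
brute_expression_count <- function(text, expressions) {
  toks <- tokenize_text(text)$token
  etoks <- lapply(expressions, function(e) tokenize_text(e)$token)
  etoks <- etoks[lengths(etoks) > 0]
  count <- 0L; i <- 1
  while (i <= length(toks)) {
    lens <- vapply(etoks, function(e) {
      k <- length(e)
      if (i + k - 1 <= length(toks) &&
          identical(toks[i:(i + k - 1)], e)) k else 0L
    }, integer(1))
    if (length(lens) && max(lens) > 0) {
      count <- count + 1L
      i <- i + max(lens)
    } else i <- i + 1
  }
  count
}

# Minimal complete lexicon set, built in code, for tests that do not need
# the bundled fixtures.
tiny_lexicons <- function() {
  lexicon_set(
    lexicon("physical", c("douleur", "mal au dos")),
    lexicon("psychic", c("angoisse", "moral à zéro")),
    lexicon("activity", c("arrêt de travail")),
    lexicon("relational", c("isolement")),
    lexicon("financial", c("dettes")),
    lexicon("positive", c("content")),
    lexicon("negative", c("horrible")),
    lexicon("anger", c("furieux")),
    lexicon("disgust", c("écœuré")),
    lexicon("fear", c("panique")),
    lexicon("joy", c("joie")),
    lexicon("sadness", c("triste")),
    lexicon("surprise", c("étonné"))
  )
}

tiny_corpus <- function(texts, ids = sprintf("m%03d", seq_along(texts))) {
  qol_corpus(ids, normalize_text(texts), source = "test")
}

# Random word soup in normalized form, for property tests.
random_texts <- function(n, vocab, min_tokens = 3, max_tokens = 30) {
  vapply(seq_len(n), function(i) {
    paste(sample(vocab, sample(min_tokens:max_tokens, 1), replace = TRUE),
          collapse = " ")
  }, character(1))
}
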