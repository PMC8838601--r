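test_that("the rule tagger resolves pronouns, tenses and participles", {
  t1 <- tag_morphology(c("je", "ne", "dors", "pas"))
  expect_identical(t1$pos, c("pronoun", "other", "verb", "other"))
  expect_identical(t1$person[1], "1sg")
  expect_identical(t1$tense[3], "present")

  t2 <- tag_morphology(c("nous", "avons", "mangé"))
  expect_identical(t2$person[1], "1pl")
  expect_identical(t2$tense[2], "present")
  expect_identical(t2$form[3], "past_participle")

  t3 <- tag_morphology(c("il", "travaillait", "et", "je", "travaille"))
  expect_identical(t3$tense[2], "past")
  expect_identical(t3$tense[5], "present")
  expect_identical(t3$form[2], "finite")

  expect_identical(nrow(tag_morphology(character(0))), 0L)
  # non-verbs carry no tense or form
  t4 <- tag_morphology(c("forum", "santé"))
  expect_true(all(t4$tense == "none" & t4$form == "none"))
})

test_that("a custom tagger function is honored", {
  silly <- function(tokens) {
    data.frame(token = tokens, pos = "other", person = "none",
               tense = "none", form = "none", stringsAsFactors = FALSE)
  }
  out <- tag_morphology(c("je", "dors"), silly)
  expect_true(all(out$pos == "other"))
})

test_that("lexical-field scores count leftmost-longest non-overlapping hits", {
  lex2 <- lexicon("physical", c("mal au dos"))
  expect_identical(
    lexical_field_score("j'ai mal au dos et encore mal au dos", lex2), 2L)
  expect_identical(
    lexical_field_score("rien ici", lexicon("physical", character(0))), 0L)
  # longest wins over its own prefix
  both <- lexicon("physical", c("mal", "mal au dos"))
  expect_identical(lexical_field_score("un mal au dos tenace", both), 1L)
  expect_identical(lexical_field_score("un mal de mer", both), 1L)
  # token anchoring: no mid-word hits
  expect_identical(lexical_field_score("normalement tout va", both), 0L)
})

test_that("expression counts match the exhaustive matcher on random texts", {
  lex <- fixture_lexicons()
  vocab <- unique(unlist(lapply(qol_dimensions(), function(d) {
    unlist(strsplit(unclass(lex[[d]]), " "))
  })))
  vocab <- c(vocab, "bonjour", "forum", "merci", "depuis", "hier")
  set.seed(23)
  texts <- random_texts(200, vocab, 3, 25)
  for (d in qol_dimensions()) {
    exprs <- unclass(lex[[d]])
    for (txt in texts[1:50]) {
      expect_identical(lexical_field_score(txt, lex[[d]]),
                       brute_expression_count(txt, exprs))
    }
  }
})

test_that("sentiment categories are counted independently", {
  lex <- tiny_lexicons()
  counts <- sentiment_counts("une panique totale hier soir", lex)
  expect_identical(counts[["fear"]], 1L)
  expect_identical(sum(counts), 1L)
  # the same word listed in two categories scores in both
  shared <- lexicon_set(c(unclass(lex)[setdiff(names(lex), c("fear", "sadness"))],
    list(lexicon("fear", c("panique", "effroi")),
         lexicon("sadness", c("panique", "larmes")))))
  counts2 <- sentiment_counts("une panique totale", shared)
  expect_identical(counts2[["fear"]], 1L)
  expect_identical(counts2[["sadness"]], 1L)
})

test_that("negation counting follows the ne...pas pairing rules", {
  toks <- function(s) tokenize_text(s)$token
  expect_identical(negation_count(toks("je ne dors pas")), 1L)
  expect_identical(not_count(toks("je ne dors pas")), 1L)
  expect_identical(not_count(toks("pas de douleur pas de stress")), 2L)
  expect_identical(negation_count(toks("je dors bien")), 0L)
  expect_identical(not_count(toks("je dors bien")), 0L)
  expect_identical(negation_count(toks("je n'en peux plus")), 1L)
  expect_identical(negation_count(toks("il ne veut rien faire")), 1L)
})

test_that("feature extraction yields the fixed 25-column inventory", {
  lex <- fixture_lexicons()
  corp <- tiny_corpus(c("j'ai une douleur depuis hier",
                        "bonjour tout le monde"))
  f <- extract_features(corp, lex)
  expect_identical(names(f), c("message_id", feature_inventory()))
  expect_identical(nrow(f), 2L)
  expect_identical(f$lex_physical, c(1L, 0L))
  other_lex <- paste0("lex_", setdiff(qol_dimensions(), "physical"))
  expect_true(all(as.matrix(f[other_lex]) == 0))
  expect_identical(f$n_first_singular[1], 1L)
  expect_true(all(as.matrix(f[, -1]) >= 0))
  # determinism
  expect_identical(extract_features(corp, lex), f)
  # incomplete set is a configuration error naming the gap
  incomplete <- lexicon_set(lexicon("physical", "douleur"))
  expect_error(extract_features(corp, incomplete), "psychic")
})

test_that("lexical scores equal planted counts on noise-free corpora", {
  sc <- generate_corpus(generator_spec(n = 60, seed = 19, noise = 0))
  f <- extract_features(sc$corpus, fixture_lexicons())
  for (d in qol_dimensions()) {
    planted <- vapply(sc$corpus$id, function(id) {
      sum(sc$expressions$message_id == id & sc$expressions$dimension == d)
    }, integer(1), USE.NAMES = FALSE)
    expect_identical(f[[paste0("lex_", d)]], planted)
  }
})

test_that("adding an expression never decreases a lexicon's score", {
  sc <- generate_corpus(generator_spec(n = 30, seed = 3))
  base <- fixture_lexicons()$physical
  grown <- lexicon("physical", c(unclass(base), "rendez-vous"))
  for (txt in sc$corpus$text[1:10]) {
    expect_gte(lexical_field_score(txt, grown),
               lexical_field_score(txt, base))
  }
})

test_that("max-normalization scales into [0,1] after median imputation", {
  f <- structure(data.frame(message_id = c("a", "b", "c"),
                            x = c(2, 4, 8), y = c(1, NA, 3),
                            z = c(0, 0, 0), stringsAsFactors = FALSE),
                 class = c("qol_features", "data.frame"))
  st <- fit_normalization(f)
  expect_identical(st$max[["x"]], 8)
  expect_identical(st$median[["y"]], 2)
  norm <- apply_normalization(f, st)
  expect_identical(norm$x, c(0.25, 0.5, 1.0))
  expect_equal(norm$y, c(1 / 3, 2 / 3, 1), tolerance = 1e-12)
  expect_identical(norm$z, c(0, 0, 0))  # max-zero feature maps to 0
  expect_error(fit_normalization(f[0, ]), "empty")
})

test_that("normalized training matrices are in [0,1] with max cells at 1", {
  sc <- generate_corpus(generator_spec(n = 50, seed = 29))
  f <- extract_features(sc$corpus, fixture_lexicons())
  st <- fit_normalization(f)
  norm <- apply_normalization(f, st)
  m <- as.matrix(norm[, -1])
  expect_true(all(m >= 0 & m <= 1))
  for (cl in feature_inventory()) {
    if (st$max[[cl]] > 0) expect_equal(max(norm[[cl]]), 1)
  }
  # unseen data beyond the training max is clipped to 1
  f2 <- f
  f2$n_chars <- f2$n_chars * 10
  expect_true(all(apply_normalization(f2, st)$n_chars <= 1))
  # state round-trips through JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization(st, path)
  st2 <- read_normalization(path)
  expect_equal(st2$max, st$max)
  expect_equal(st2$median, st$median)
})
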