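# Neutral French filler sentences used to pad synthetic messages. By
# construction they contain no fixture lexicon expression and no fixture
# dictionary term (a unit test enforces this), so lexical-field scores of
# generated messages equal the planted-expression counts when noise is 0.
.filler_sentences <- c(
  "bonjour à tous sur ce forum.",
  "merci d'avance pour vos réponses.",
  "voilà un peu mon parcours jusqu'ici.",
  "je voulais partager mon expérience ici.",
  "avez-vous déjà vécu quelque chose de semblable ?",
  "je lis ce forum depuis longtemps.",
  "chaque situation est différente je pense.",
  "mon médecin doit me rappeler la semaine prochaine.",
  "j'attends les résultats des examens.",
  "on verra la suite dans quelques semaines.",
  "courage à toutes et à tous.",
  "je reviendrai donner des nouvelles bientôt.",
  "c'est la première fois que je poste.",
  "désolé pour la longueur du message.",
  "n'hésitez pas à me poser des questions.",
  "le rendez-vous est prévu le mois prochain.",
  "je note tout dans un carnet.",
  "la salle d'attente était pleine hier.",
  "le secrétariat ne répond que le matin.",
  "il faut prévoir un dossier complet."
)

# Carrier templates: planted expressions are embedded in these sentences,
# first-person for impacted messages, impersonal for stray expressions.
.impact_carriers <- c(
  "je vis avec %s depuis des mois.",
  "pour moi c'est %s en ce moment.",
  "au quotidien cela donne %s malheureusement.",
  "je dirais surtout %s ces derniers temps."
)
.stray_carriers <- c(
  "certains évoquent %s sur ce forum.",
  "on parle parfois de %s ici."
)
.term_carriers <- c(
  "la discussion porte sur %s en ce moment.",
  "beaucoup de messages mentionnent %s sur ce fil."
)

#' Bundled fixture lexicons
#'
#' Open French fixture lexicons for the five HRQoL dimensions and the
#' eight sentiment categories, shipped with the package (standing in, with
#' the same file shape, for annotation-harvested dimension lexicons and a
#' licensed psycholinguistic dictionary).
#'
#' @return A complete [lexicon_set].
#' @export
fixture_lexicons <- function() {
  read_lexicons(system.file("extdata", "lexicons.json",
                            package = "qolminer", mustWork = TRUE))
}

#' Bundled fixture term dictionary
#'
#' A small synthetic drug/disease dictionary of the shape used by the
#' health-related message filter.
#'
#' @return A [term_dictionary].
#' @export
fixture_dictionary <- function() {
  read_term_dictionary(system.file("extdata", "terms.csv",
                                   package = "qolminer", mustWork = TRUE),
                       match_mode = "approximate")
}

#' Specify a synthetic corpus
#'
#' Defaults emulate the study conditions of the real forum corpus: the
#' per-label prevalences (impact 58%, physical 31%, psychic 37%, activity
#' 25%, relational 13%, financial 4%) and the message length distribution
#' (lognormal, mean 905 characters, SD 1041).
#'
#' @param n number of messages.
#' @param prevalence named numeric vector of marginal prevalences for
#'   `impact` and the five dimensions; each dimension prevalence must not
#'   exceed the impact prevalence.
#' @param signal expected planted-expression count per positive dimension
#'   (Poisson, truncated below at 1 so every positive flag has at least one
#'   planted expression).
#' @param noise probability that a message receives one stray expression
#'   of a dimension it is not flagged for.
#' @param length_mean,length_sd target mean and SD of message length in
#'   characters (lognormal model).
#' @param health_term_rate probability that a message contains a
#'   dictionary term.
#' @param seed integer seed.
#' @return A list of class `qol_generator_spec`.
#' @export
generator_spec <- function(n = 1399L,
                           prevalence = c(impact = 0.58, physical = 0.31,
                                          psychic = 0.37, activity = 0.25,
                                          relational = 0.13,
                                          financial = 0.04),
                           signal = 2.0, noise = 0.02,
                           length_mean = 905, length_sd = 1041,
                           health_term_rate = 1.0, seed = 7L) {
  stopifnot(n >= 1)
  needed <- c("impact", qol_dimensions())
  miss <- setdiff(needed, names(prevalence))
  if (length(miss)) {
    stop("prevalence lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(prevalence[qol_dimensions()] > prevalence[["impact"]])) {
    stop("dimension prevalence cannot exceed impact prevalence",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), prevalence = prevalence[needed],
                 signal = signal, noise = noise,
                 length_mean = length_mean, length_sd = length_sd,
                 health_term_rate = health_term_rate,
                 seed = as.integer(seed)),
            class = "qol_generator_spec")
}

#' Generate a labeled synthetic forum corpus
#'
#' Per message: the impact flag is drawn Bernoulli(impact prevalence); for
#' impacted messages each dimension flag is drawn
#' Bernoulli(dimension prevalence / impact prevalence), redrawn until at
#' least one dimension is positive. Each positive dimension receives a
#' truncated-Poisson number of expressions sampled from its lexicon,
#' embedded in first-person carrier sentences; with probability `noise`
#' the message receives one stray expression of an unflagged dimension;
#' with probability `health_term_rate` a dictionary term is embedded.
#' Neutral filler sentences pad the message toward a lognormal length
#' draw. Sentence order is shuffled; the exact character span of every
#' planted expression in the final text is recorded. Deterministic given
#' the spec's seed.
#'
#' @param spec a [generator_spec].
#' @param lexicons complete [lexicon_set]; default the bundled fixtures.
#' @param dictionary a [term_dictionary]; default the bundled fixture.
#' @return An object of class `qol_synthetic_corpus`: list with `corpus`
#'   (a [qol_corpus]), `labels` (gold label table), `expressions` (planted
#'   spans: `message_id`, `start`, `end`, `dimension`), `term_ids`
#'   (ids of messages holding a dictionary term) and `spec`.
#' @export
generate_corpus <- function(spec = generator_spec(),
                            lexicons = fixture_lexicons(),
                            dictionary = fixture_dictionary()) {
  stopifnot(inherits(spec, "qol_generator_spec"))
  miss <- missing_lexicons(lexicons)
  if (length(miss)) {
    stop("incomplete lexicon set; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dims <- qol_dimensions()
  p <- spec$prevalence
  for (d in dims) {
    if (p[[d]] > 0 && length(lexicons[[d]]) == 0) {
      stop("dimension `", d, "` has prevalence ", p[[d]],
           " but an empty lexicon", call. = FALSE)
    }
  }
  # lognormal parameters matching the target mean and SD
  cv2 <- (spec$length_sd / spec$length_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(spec$length_mean) - sdlog^2 / 2
  # Calibrate the per-dimension Bernoulli rates so that, after the
  # redraw-until-one-positive conditioning, each dimension's conditional
  # marginal equals prevalence.dim / prevalence.impact — hence the overall
  # marginal equals prevalence.dim. Fixed point of q = m * (1 - prod(1-q)).
  m <- vapply(dims, function(d) {
    if (p[["impact"]] > 0) p[[d]] / p[["impact"]] else 0
  }, numeric(1))
  q <- m
  # a non-trivial fixed point exists only when sum(m) > 1; otherwise keep
  # the uncalibrated rates (their conditional inflation is then unavoidable)
  if (sum(m) > 1 && max(m) < 1) {
    for (it in 1:100) q <- m * (1 - prod(1 - q))
  }
  set.seed(spec$seed)
  ids <- sprintf("synth-%06d", seq_len(spec$n))
  texts <- character(spec$n)
  impact <- logical(spec$n)
  dim_flags <- matrix(FALSE, spec$n, length(dims),
                      dimnames = list(NULL, dims))
  span_rows <- list()
  term_ids <- character(0)
  for (i in seq_len(spec$n)) {
    impacted <- stats::runif(1) < p[["impact"]]
    flags <- stats::setNames(rep(FALSE, length(dims)), dims)
    if (impacted) {
      repeat {
        flags <- stats::setNames(stats::runif(length(dims)) < q, dims)
        if (any(flags)) break
      }
    }
    # sentences holding a planted expression: (sentence, dimension,
    # offset of the expression within the sentence, expression length)
    planted <- list()
    for (d in dims[flags]) {
      k <- max(1L, stats::rpois(1, spec$signal))
      exprs <- sample(unclass(lexicons[[d]]), k, replace = TRUE)
      for (e in exprs) {
        tmpl <- sample(.impact_carriers, 1)
        off <- regexpr("%s", tmpl, fixed = TRUE)[1] - 1L
        planted[[length(planted) + 1]] <-
          list(sentence = sprintf(tmpl, e), dimension = d,
               offset = off, len = nchar(e))
      }
    }
    if (stats::runif(1) < spec$noise) {
      off_dims <- dims[!flags]
      if (length(off_dims) > 0) {
        d <- if (length(off_dims) == 1) off_dims else sample(off_dims, 1)
        e <- sample(unclass(lexicons[[d]]), 1)
        tmpl <- sample(.stray_carriers, 1)
        # stray expressions are noise: present in the text, absent from
        # the gold spans
        planted[[length(planted) + 1]] <-
          list(sentence = sprintf(tmpl, e), dimension = NA_character_,
               offset = NA_integer_, len = NA_integer_)
      }
    }
    sentences <- lapply(planted, `[[`, "sentence")
    meta <- planted
    if (stats::runif(1) < spec$health_term_rate) {
      term <- dictionary$surface[sample.int(nrow(dictionary), 1)]
      tmpl <- sample(.term_carriers, 1)
      sentences <- c(sentences, sprintf(tmpl, term))
      meta <- c(meta, list(NULL))
      term_ids <- c(term_ids, ids[i])
    }
    target_len <- min(stats::rlnorm(1, meanlog, sdlog), 6000)
    current <- sum(vapply(sentences, nchar, numeric(1))) +
      max(0, length(sentences) - 1)
    while (current < target_len) {
      filler <- sample(.filler_sentences, 1)
      sentences <- c(sentences, filler)
      meta <- c(meta, list(NULL))
      current <- current + nchar(filler) + 1
    }
    if (length(sentences) == 0) {
      sentences <- list(sample(.filler_sentences, 1))
      meta <- list(NULL)
    }
    ord <- sample.int(length(sentences))
    sentences <- sentences[ord]
    meta <- meta[ord]
    texts[i] <- paste(unlist(sentences), collapse = " ")
    # global 0-based offsets of planted expressions
    cursor <- 0L
    for (s in seq_along(sentences)) {
      m <- meta[[s]]
      if (!is.null(m) && !is.na(m$dimension)) {
        start <- cursor + m$offset
        span_rows[[length(span_rows) + 1]] <- data.frame(
          message_id = ids[i], start = start, end = start + m$len,
          dimension = m$dimension, stringsAsFactors = FALSE)
      }
      cursor <- cursor + nchar(sentences[[s]]) + 1L
    }
    impact[i] <- any(flags)
    dim_flags[i, ] <- flags
  }
  corpus <- qol_corpus(ids, texts, source = "synthetic",
                       provenance = sprintf("generator seed %d", spec$seed))
  labels <- data.frame(message_id = ids, annotator = "generator",
                       impact = impact, stringsAsFactors = FALSE)
  for (d in dims) labels[[d]] <- dim_flags[, d]
  expressions <- if (length(span_rows)) do.call(rbind, span_rows) else
    data.frame(message_id = character(0), start = integer(0),
               end = integer(0), dimension = character(0),
               stringsAsFactors = FALSE)
  structure(list(corpus = corpus, labels = labels,
                 expressions = expressions,
                 term_ids = unique(term_ids), spec = spec),
            class = "qol_synthetic_corpus")
}

#' @export
print.qol_synthetic_corpus <- function(x, ...) {
  cat(sprintf("<qol_synthetic_corpus> %d messages (seed %d)\n",
              nrow(x$corpus), x$spec$seed))
  cat(sprintf("  impacted: %d | planted expressions: %d | with term: %d\n",
              sum(x$labels$impact), nrow(x$expressions),
              length(x$term_ids)))
  invisible(x)
}

#' Generate a labeled numeric feature table
#'
#' Text-free companion generator for exercising the modeling layer:
#' informative features are drawn from class-shifted Gaussians
#' (`N(0, 1)` for negatives, `N(effect_size, 1)` for positives), noise
#' features are class-independent `N(0, 1)`.
#'
#' @param n number of rows.
#' @param p_informative number of informative features (at least 1).
#' @param p_noise number of noise features.
#' @param imbalance positive-class fraction; the implied minority must
#'   have at least 2 rows.
#' @param effect_size mean shift of informative features for positives.
#' @param seed integer seed.
#' @return A list with `X` (named numeric matrix), `y` (0/1 integer
#'   vector) and `informative` (names of the informative columns).
#' @export
generate_feature_table <- function(n, p_informative, p_noise,
                                   imbalance = 0.5, effect_size = 1,
                                   seed = 1L) {
  stopifnot(p_informative >= 1, p_noise >= 0)
  n_pos <- round(n * imbalance)
  if (min(n_pos, n - n_pos) < 2) {
    stop("imbalance leaves fewer than 2 rows in the minority class",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  inf <- matrix(stats::rnorm(n * p_informative), n, p_informative) +
    effect_size * y
  noise <- if (p_noise > 0) {
    matrix(stats::rnorm(n * p_noise), n, p_noise)
  } else NULL
  X <- cbind(inf, noise)
  colnames(X) <- c(sprintf("inf%d", seq_len(p_informative)),
                   if (p_noise > 0) sprintf("noise%d", seq_len(p_noise)))
  list(X = X, y = y, informative = sprintf("inf%d", seq_len(p_informative)))
}
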