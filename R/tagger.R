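# Closed word lists for the rule-based French tagger. The inventory is
# deliberately small: enough coverage for informal forum French that the
# grammar/conjugation counts carry signal, fully deterministic, no model
# download. Tokens carry the elision apostrophe ("j'", "n'").

.fr_pronouns_1sg <- c("je", "j'", "me", "m'", "moi")
.fr_pronouns_1pl <- c("nous")
.fr_pronouns_other <- c(
  "tu", "te", "t'", "toi", "il", "elle", "on", "vous", "ils", "elles",
  "se", "s'", "lui", "leur", "eux", "celui", "celle", "ceux", "celles",
  "cela", "ceci"
)

.fr_infinitives <- c(
  "être", "avoir", "faire", "dire", "pouvoir", "aller", "voir", "savoir",
  "vouloir", "venir", "devoir", "prendre", "trouver", "donner", "parler",
  "mettre", "passer", "regarder", "aimer", "croire", "demander", "rester",
  "répondre", "vivre", "dormir", "manger", "travailler", "arrêter",
  "sortir", "marcher", "penser", "sentir", "souffrir", "pleurer", "payer",
  "changer", "perdre", "gagner", "porter", "garder", "appeler",
  "comprendre", "attendre", "laisser", "écrire", "lire", "jouer",
  "courir", "tenir", "finir", "commencer", "continuer", "essayer",
  "espérer", "chercher", "aider", "poser", "partager", "revenir",
  "reprendre", "noter", "remercier", "rappeler", "consulter",
  "ressentir", "coûter", "rembourser", "gérer", "supporter", "assumer",
  "expliquer", "raconter", "annuler", "renoncer"
)

.fr_present_forms <- c(
  "suis", "es", "est", "sommes", "êtes", "sont",
  "ai", "as", "a", "avons", "avez", "ont",
  "fais", "faisons", "faites", "font",
  "vais", "vas", "va", "allons", "allez", "vont",
  "peux", "peut", "pouvons", "pouvez", "peuvent",
  "veux", "veut", "voulons", "voulez", "veulent",
  "dois", "doit", "devons", "devez", "doivent",
  "sais", "sait", "savons", "savez", "savent",
  "prends", "prend", "prenons", "prenez", "prennent",
  "dors", "dort", "dormons", "dormez", "dorment",
  "vis", "vit", "vivons", "vivez", "vivent",
  "sens", "sent", "sentons", "sentez", "sentent",
  "souffre", "souffres", "souffrons", "souffrez", "souffrent",
  "viens", "vient", "venons", "venez", "viennent",
  "mets", "met", "mettons", "mettez", "mettent",
  "perds", "perd", "perdons", "perdez", "perdent",
  "comprends", "comprend", "comprenons", "comprennent",
  "attends", "attend", "attendons", "attendent",
  "tiens", "tient", "tenons", "tiennent",
  "finis", "finit", "finissons", "finissent",
  "crois", "croit", "croyons", "croient",
  "vois", "voit", "voyons", "voient",
  "dis", "dit", "disons", "dites", "disent"
)

.fr_past_forms <- c(
  "étais", "était", "étions", "étiez", "étaient",
  "avais", "avait", "avions", "aviez", "avaient",
  "faisais", "faisait", "faisaient",
  "pouvais", "pouvait", "pouvaient",
  "devais", "devait", "devaient",
  "voulais", "voulait", "voulaient",
  "allais", "allait", "allaient",
  "fus", "fut", "furent", "eus", "eut", "eurent"
)

.fr_participles_irregular <- c(
  "pris", "fait", "mis", "eu", "été", "vu", "su", "pu", "dû",
  "voulu", "venu", "tenu", "perdu", "répondu", "vécu", "dormi",
  "souffert", "sorti", "fini", "compris", "attendu", "écrit", "lu",
  "couru", "ressenti", "prescrit", "devenu", "reçu", "connu"
)

.fr_negators <- c("pas", "plus", "jamais", "rien", "personne",
                  "aucun", "aucune", "guère")

#' Rule-based French morphology tagger
#'
#' Returns the bundled deterministic tagger: closed word lists for pronouns
#' (with first-person singular/plural markers), verb infinitives, present
#' and imperfect finite forms, and irregular past participles, plus suffix
#' rules (regular `-é/-ée/-és/-ées` participles, `-e/-es/-ons/-ez/-ent`
#' present and `-ais/-ait/-ions/-iez/-aient` imperfect endings checked
#' against the infinitive list). Any tagger can be substituted: a tagger is
#' either an object of this class or a function mapping a token vector to a
#' tag data frame with columns `token`, `pos`, `person`, `tense`, `form`.
#'
#' @return An object of class `qol_tagger`.
#' @export
french_tagger <- function() {
  structure(list(pronouns_1sg = .fr_pronouns_1sg,
                 pronouns_1pl = .fr_pronouns_1pl,
                 pronouns_other = .fr_pronouns_other,
                 infinitives = .fr_infinitives,
                 present_forms = .fr_present_forms,
                 past_forms = .fr_past_forms,
                 participles_irregular = .fr_participles_irregular),
            class = "qol_tagger")
}

.strip_ending <- function(token, ending) {
  substr(token, 1, nchar(token) - nchar(ending))
}

# Try to resolve a suffixed form to a known infinitive; returns TRUE when
# stem + one of the given conjugation classes is in the verb list.
.stem_known <- function(stem, infinitives, classes = c("er", "ir", "re", "oir")) {
  any(paste0(stem, classes) %in% infinitives)
}

#' Tag tokens with morphological features
#'
#' One tag per token. Non-verbs carry `tense = "none"` and `form = "none"`;
#' unknown tokens are tagged `pos = "other"` (never missing).
#'
#' @param tokens character vector of normalized tokens (see
#'   [tokenize_text()]).
#' @param tagger a tagger as returned by [french_tagger()], or a function
#'   `tokens -> data.frame(token, pos, person, tense, form)`.
#' @return A data frame with columns `token`, `pos` (`verb`, `pronoun`,
#'   `other`), `person` (`1sg`, `1pl`, `other`, `none`), `tense`
#'   (`present`, `past`, `none`), `form` (`infinitive`, `past_participle`,
#'   `finite`, `none`).
#' @export
tag_morphology <- function(tokens, tagger = french_tagger()) {
  if (is.function(tagger)) {
    out <- tagger(tokens)
    stopifnot(all(c("token", "pos", "person", "tense", "form") %in% names(out)))
    return(out)
  }
  stopifnot(inherits(tagger, "qol_tagger"))
  n <- length(tokens)
  pos <- rep("other", n); person <- rep("none", n)
  tense <- rep("none", n); form <- rep("none", n)
  for (i in seq_len(n)) {
    tk <- tokens[i]
    if (tk %in% tagger$pronouns_1sg) {
      pos[i] <- "pronoun"; person[i] <- "1sg"
    } else if (tk %in% tagger$pronouns_1pl) {
      pos[i] <- "pronoun"; person[i] <- "1pl"
    } else if (tk %in% tagger$pronouns_other) {
      pos[i] <- "pronoun"; person[i] <- "other"
    } else if (tk %in% tagger$infinitives) {
      pos[i] <- "verb"; form[i] <- "infinitive"
    } else if (tk %in% tagger$participles_irregular) {
      pos[i] <- "verb"; form[i] <- "past_participle"
    } else if (grepl("(é|ée|és|ées)$", tk) &&
               .stem_known(sub("é(es?|s)?$", "", tk), tagger$infinitives, "er")) {
      pos[i] <- "verb"; form[i] <- "past_participle"
    } else if (tk %in% tagger$present_forms) {
      pos[i] <- "verb"; tense[i] <- "present"; form[i] <- "finite"
    } else if (tk %in% tagger$past_forms) {
      pos[i] <- "verb"; tense[i] <- "past"; form[i] <- "finite"
    } else {
      matched <- FALSE
      for (ending in c("aient", "ions", "iez", "ais", "ait")) {
        if (endsWith(tk, ending) && nchar(tk) > nchar(ending) + 1 &&
            .stem_known(.strip_ending(tk, ending), tagger$infinitives)) {
          pos[i] <- "verb"; tense[i] <- "past"; form[i] <- "finite"
          matched <- TRUE; break
        }
      }
      if (!matched) {
        for (ending in c("ent", "ons", "ez", "es", "e")) {
          if (endsWith(tk, ending) && nchar(tk) > nchar(ending) + 1 &&
              .stem_known(.strip_ending(tk, ending), tagger$infinitives, "er")) {
            pos[i] <- "verb"; tense[i] <- "present"; form[i] <- "finite"
            break
          }
        }
      }
    }
  }
  data.frame(token = tokens, pos = pos, person = person, tense = tense,
             form = form, stringsAsFactors = FALSE)
}

#' Count French negation constructions
#'
#' Counts `ne`/`n'` ... `pas`/`plus`/`jamais`/`rien`/... pairs (the second
#' element searched within the four tokens after the `ne`), plus bare `pas`
#' tokens not already consumed by a pair.
#'
#' @param tokens character vector of normalized tokens.
#' @return Non-negative integer count.
#' @export
negation_count <- function(tokens) {
  n <- length(tokens)
  if (n == 0) return(0L)
  consumed <- logical(n)
  count <- 0L
  for (i in seq_len(n)) {
    if (tokens[i] %in% c("ne", "n'")) {
      window <- seq(i + 1, min(i + 4, n))
      if (i + 1 > n) next
      hit <- window[tokens[window] %in% .fr_negators & !consumed[window]]
      if (length(hit)) {
        count <- count + 1L
        consumed[hit[1]] <- TRUE
      }
    }
  }
  count + sum(tokens == "pas" & !consumed)
}

#' Count occurrences of the bare negator "pas"
#'
#' The closest French equivalent of English "not"; counted independently of
#' whether the token belongs to a `ne ... pas` pair.
#'
#' @param tokens character vector of normalized tokens.
#' @return Non-negative integer count.
#' @export
not_count <- function(tokens) {
  sum(tokens == "pas")
}
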