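{
  "physical": [
    "douleur",
    "mal au dos",
    "fatigue intense",
    "épuisé",
    "nausées",
    "vertiges",
    "insomnie",
    "maux de tête",
    "douleurs articulaires",
    "essoufflé au moindre effort",
    "démangeaisons",
    "bouffées de chaleur"
  ],
  "psychic": [
    "angoisse",
    "déprime",
    "anxiété",
    "idées noires",
    "moral à zéro",
    "crise de panique",
    "peur de l'avenir",
    "tristesse profonde",
    "colère permanente",
    "découragé",
    "ruminations",
    "stress constant"
  ],
  "activity": [
    "arrêt de travail",
    "impossible de travailler",
    "plus de sport",
    "mi-temps thérapeutique",
    "tâches ménagères impossibles",
    "activités quotidiennes limitées",
    "absences répétées au bureau",
    "incapable de conduire",
    "renoncé à mes loisirs",
    "journées improductives"
  ],
  "relational": [
    "isolement",
    "disputes fréquentes",
    "mon couple en souffre",
    "coupé de mes amis",
    "vie de famille perturbée",
    "conflits avec mes proches",
    "repli sur soi",
    "vie sociale réduite",
    "incompréhension de mon entourage",
    "éloigné de tout le monde"
  ],
  "financial": [
    "frais médicaux élevés",
    "dépassements d'honoraires",
    "perte de revenus",
    "fins de mois difficiles",
    "dettes qui s'accumulent",
    "reste à charge important",
    "budget serré",
    "précarité",
    "crédit refusé",
    "mutuelle insuffisante"
  ],
  "positive": [
    "content",
    "heureuse",
    "heureux",
    "soulagement",
    "optimiste",
    "apaisé",
    "confiant",
    "agréable",
    "espoir",
    "satisfait"
  ],
  "negative": [
    "mauvais",
    "pire",
    "horrible",
    "pénible",
    "insupportable",
    "terrible",
    "affreux",
    "détestable",
    "négatif",
    "calvaire"
  ],
  "anger": [
    "colère",
    "énervé",
    "furieux",
    "rage",
    "agacé",
    "révolté",
    "exaspéré",
    "irrité"
  ],
  "disgust": [
    "dégoût",
    "écœuré",
    "répugnant",
    "dégoûté",
    "nauséabond",
    "rebuté"
  ],
  "fear": [
    "peur",
    "effrayé",
    "terrifié",
    "crainte",
    "panique",
    "redoute",
    "angoissé",
    "apeuré"
  ],
  "joy": [
    "joie",
    "ravi",
    "sourire",
    "bonheur",
    "enthousiaste",
    "réjoui",
    "gaieté"
  ],
  "sadness": [
    "triste",
    "tristesse",
    "pleure",
    "chagrin",
    "larmes",
    "abattu",
    "morose",
    "mélancolie"
  ],
  "surprise": [
    "surpris",
    "étonné",
    "stupéfait",
    "inattendu",
    "choc",
    "sidéré",
    "ébahi",
    "interloqué"
  ]
}
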