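---
title: "Detecting quality-of-life impacts in patient forum messages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting quality-of-life impacts in patient forum messages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolminer)
```

## The problem and the model

Patients describe, in free text on health forums, how a disease or a
treatment affects their daily life. `qolminer` detects such mentions of a
health-related quality of life (HRQoL) impact and attributes each one to
five dimensions inspired by the EQ-5D / SF-36 questionnaire domains:
**physical**, **psychic**, **activity-related**, **relational** and
**financial**.

The classifier is a *two-stage gated hierarchy*. A first binary model
decides whether a message expresses any impact at all; only messages
flagged by this stage are passed to five per-dimension binary models. The
gating is enforced at prediction time: a message with `impact_flag =
FALSE` can never carry a dimension flag, and its dimension probabilities
are reported as absent. The rationale is that dimension-specific vocabulary
is meaningful only once an impact is present, and that separate models per
dimension can each use the feature subset best suited to their own
vocabulary.

Messages are represented by 25 fixed, interpretable, non-negative
features (`feature_inventory()`):

* five **lexical-field scores** — counts of dimension-specific expressions
  (the vocabulary patients use when voicing that kind of impact, as
  harvested from annotation with `build_lexicon_from_annotations()`);
* eight **sentiment counts** (positive, negative, anger, disgust, fear,
  joy, sadness, surprise) driven by word lists of the same shape as
  psycholinguistic dictionaries such as LIWC;
* five **grammar counts** — pronouns, first-person singular markers
  ("who is writing" about themselves), first-person plural markers
  (impacts on the family tend to be voiced with *nous*), negation
  constructions (*ne ... pas/plus/jamais/rien*), and bare *pas* tokens;
* four **conjugation counts** — infinitives, present-tense and
  imperfect-tense finite verbs, past participles;
* three **structure features** — characters, tokens, sentences.

Counting is token-boundary-anchored with leftmost-longest resolution, so
*mal au dos* beats *mal* and *rage* never fires inside *courage*.

## Preprocessing contracts

All text is normalized once (`normalize_text()`): Unicode NFC, lowercase
(locale-independent), HTML entities decoded, URLs replaced by the single
token `<url>` (so token counts survive), whitespace collapsed. Every
character offset in the package — term mentions, captured annotation
spans, planted generator spans — refers to this normalized text, 0-based,
half-open. Deduplication removes messages whose normalized text is
byte-identical to an earlier one; the rule is exact rather than fuzzy so
that removals are auditable. Sentence splitting is rule-based with a
configurable abbreviation stop list (*dr.*, *etc.*, ...); it requires no
model download and is exactly reconstructible.

Health-related messages are selected by dictionary matching of drug and
disease mentions (`match_terms()`). Approximate matching uses a
Levenshtein budget scaled by surface length — 0 edits under 5 characters,
at most 1 for 5–9, at most 2 for 10 or more — which tolerates the typical
one-letter misspellings of long drug names (*levothirox*) while never
letting short terms drift. Overlaps resolve leftmost-longest, then lowest
distance. The bundled `terms.csv` is a small synthetic fixture of the
same shape as a licensed terminology export; it is not MedDRA content.

## Training pipeline

`hrqol_train()` runs, per model (impact + five dimensions):

1. **Normalization** — each feature is divided by its *training* maximum
   (all features are non-negative, so this maps training data into
   [0, 1]); missing values are imputed with the training median *before*
   scaling, since the median is defined on the raw scale. Values on new
   data may exceed the stored maximum and are clipped to [0, 1], keeping
   the contract everywhere. The state is fitted on training rows only.
2. **Feature selection** — sequential forward floating selection (SFFS):
   greedy additions maximizing 5-fold cross-validated AUC, each followed
   by conditional removals that strictly improve it. AUC is the scoring
   target so that rare-but-real impact mentions are not sacrificed to
   accuracy. Folds are stratified (required for the 4% financial
   dimension), created once, and reused for every candidate, so all
   comparisons are paired. Ties break on the fixed inventory order. The
   default cap of 10 selected features bounds the greedy search; in
   practice the high-signal models stop well before it.
3. **SMOTE** — the three rare dimensions (activity, relational,
   financial) are rebalanced by synthetic minority oversampling: convex
   combinations between a minority row and one of its k = 5 nearest
   minority neighbours. Oversampling happens *inside* CV training folds
   only, never in a held-out fold — oversampling before splitting leaks
   copies of validation information into training and inflates CV AUC —
   and once more on the full training set for the final fit. k is
   reduced automatically when a minority is tiny.
4. **Grid search** — exhaustive 5-fold evaluation over the boosting grid
   (`default_boosting_grid()`): learning rate {0.05, 0.1, 0.3}, rounds
   {50, 100, 200}, depth {2, 4, 6}, minimum child weight {1, 5}, minimum
   split loss {0, 1}, L1 regularization {0, 0.5}. Ties resolve to the
   first combination in grid order.
5. **Final fit** — gradient boosting by default; k-nearest neighbours,
   SVM, multi-layer perceptron and random forest are available through
   the same interface and compared with `benchmark_learners()` on shared
   folds.

Stage-2 models train on the impact-labeled subset of the training
messages (`stage2_on_impacted = TRUE`), matching what they will see at
prediction time behind the gate; training them on all messages is one
switch away. A dimension with no positive training label degrades
explicitly: the model is marked untrainable and predicts `FALSE` with a
warning, rather than failing the whole fit.

The decision threshold turning probabilities into flags is 0.5 and
configurable; nothing in the pipeline depends on it being optimal, and
ROC/AUC reporting is threshold-free.

Every stochastic step — fold assignment, SMOTE draws, learner fits — is
seeded from the single `seed` argument, so training and prediction are
bit-for-bit repeatable.

## Evaluation

`evaluate_model()` reports, per target, the confusion matrix,
sensitivity, specificity, F-measure and the ROC curve with its AUC. AUC
is computed as the Mann–Whitney pair statistic with ties counted ½, and
the trapezoidal integral of the reported curve equals it. Dimension
metrics are computed over *all* labeled messages: a message gated out by
stage 1 counts as a negative prediction with score 0 for every dimension,
so the numbers reflect end-to-end behavior rather than performance
conditional on a correct first stage. Metrics whose denominator is empty
(for instance sensitivity of a dimension absent from a small validation
set) are reported as `NA` rather than invented.

Annotation quality is audited with Cohen's kappa on a doubly annotated
subset (`agreement_report()`). When both raters are constant and
identical — as happens for a dimension never mentioned in the subset —
chance agreement is 1 and kappa is degenerate; the package returns 0 by
convention for that case.

## The synthetic corpus generator

Real patient-forum corpora cannot be redistributed, so the package ships
a generator (`generate_corpus()`) whose defaults are the study
conditions the pipeline targets: 1399 messages, marginal prevalences of
58% (any impact), 31/37/25/13/4% for the five dimensions, lognormal
message lengths with mean 905 and SD 1041 characters, one drug/disease
term per message, an expected two planted dimension expressions per
positive flag (`signal = 2`, Poisson truncated below at 1 so a positive
flag always has at least one supporting expression), and a 2% stray
expression rate in unflagged dimensions.

Two generator choices deserve a note:

* **Dimension draws.** Given an impacted message, dimension flags are
  drawn independently and redrawn until at least one is positive. The
  naive rates `p_dim / p_impact` would be inflated about 7% by that
  conditioning, so the generator solves the fixed point
  `q = m (1 − Π(1 − q))` and draws with the calibrated rates `q`,
  making the post-conditioning marginals hit the targets exactly. (When
  the rates are so small that no non-trivial fixed point exists, the
  naive rates are used as-is.) Dimensions are independent given impact;
  real co-occurrence structure is unknown, and only marginals are
  targeted.
* **Vocabulary separation.** Filler and carrier sentences are built to
  contain no lexicon expression and no dictionary term, so lexical
  scores equal planted counts exactly at `noise = 0` and the
  health-term filter recovers exactly the seeded messages — both are
  enforced by tests.

What passing on this corpus shows — and does not show. The generator
plants the very vocabulary the lexicons contain, with first-person
framing on impacted messages; it emulates the *statistical shape* of the
problem (prevalences, lengths, class imbalance, label gating), not the
linguistic difficulty of real forum French (irony, misspelling beyond
drug names, impact voiced in out-of-lexicon words). High AUCs here
validate the machinery — feature extraction, selection, rebalancing,
gating, evaluation — they do not forecast performance on real corpora,
where published systems of this design reach AUCs in the 0.70–0.79
range.

## Problem sizes and numerical choices

The bundled examples and tests run the full pipeline at the study scale
(n = 1399, 70:30 split giving 979/420) and the modeling unit tests at
n ≈ 100–250 with a reduced grid; the numeric feature-selection benchmark
uses n = 400 with 2 informative features among 10 at effect size 3.
SFFS accepts a step only when it improves CV AUC by more than 1e−6,
preventing tie-walking on plateaus. Normalization maps features with
training maximum 0 to 0 instead of dividing by zero. `split_corpus()`
sizes the training set as `floor(ratio · n)` — the only rule consistent
with a 70:30 split of 1399 messages yielding a 420-message validation
set — and splits unstratified by default (a `stratify_by` hook exists),
since nothing indicates the original protocol stratified.

## Limitations

The morphology tagger is a closed-list rule system: adequate for the
grammar and conjugation *counts* the features need, not a general French
tagger; any tagger can be plugged in as a function. Lexical matching is
literal (token-anchored substring), without inflectional expansion.
Kappa is two-rater, binary, unweighted. The bundled lexicons and
dictionary are small open fixtures; swapping in a licensed LIWC export
or a real terminology is a matter of replacing the JSON/CSV files.
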