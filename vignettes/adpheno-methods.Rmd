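---
title: "Phenotyping atopic dermatitis from clinical notes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping atopic dermatitis from clinical notes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpheno)
```

## The problem

Atopic dermatitis (AD) has no gold-standard laboratory test; cohort selection
for AD studies ultimately rests on chart review against clinical criteria such
as the UK Working Party (UKWP) rule: an itchy skin condition plus at least
three of five minor criteria (flexural involvement history, asthma or hay
fever history, dry skin history, rash onset at age two or younger, visible
flexural dermatitis). Billing codes are an unreliable proxy, and manual review
does not scale. `adpheno` implements a pipeline that reads a patient's
free-text notes and predicts whether the patient matches the AD phenotype,
so that manual review can be concentrated on plausible candidates.

## The pipeline

Every patient is reduced to an 8-element vector, one element per *indicator
category*: (1) a direct mention of AD, (2) hay fever allergies, (3) atopic
allergies, (4) eczema or rashes, (5) dry or itchy skin, (6) nonasthma
medications used to treat AD, (7) asthma, (8) asthma medications. Two
constructions of that vector are supported.

**Binary mode (rules only).** Documents are segmented into sentences; each
sentence is matched against per-category keyword lexicons; each match receives
an assertion status — `affirmed`, `negated`, `experiencer_other` or
`hypothetical` — from a ConText-style trigger/scope rule set. Element *k* is 1
exactly when at least one sentence carries an affirmed match for category *k*.

**Probability mode (embedding + MLP).** Sentences are embedded as 768-vectors.
For each category a class-balanced sentence dataset is assembled (positives:
sentences affirmed for the category; negatives: sentences affirmed in some
*other* category and not matched to this one) and a multilayer perceptron —
fully connected $768 \times 100$, ReLU, fully connected $100 \times 2$,
softmax — is trained for 10 epochs with minibatch SGD (learning rate 0.001,
momentum 0.9) on the cross-entropy loss. Element *k* of the patient vector is
the **maximum** affirm probability that classifier *k* assigns to *any*
sentence in the patient's record (all sentences are scanned, not only
lexicon-matched ones; this asymmetry with binary mode is deliberate and
preserved). An empty record yields the zero vector: the max over an empty set
is undefined, and 0 encodes "no evidence".

Downstream, the patient vectors feed a roster of standard classifiers —
logistic regression, SVM (RBF), decision tree, random forest, k-nearest
neighbours, gradient-boosted trees, AdaBoost — each tuned by 5-fold
cross-validated accuracy (ties broken by grid order) and refit on the full
training set, plus a stacking ensemble whose logistic meta-learner is trained
on out-of-fold base predictions. Evaluation uses six metrics derived from the
confusion counts: accuracy, precision, recall, F1, negative predictive value
and specificity. A metric with a zero denominator is reported as `NA`, never
coerced to 0.

### Cohort splitting

The cohort split mirrors the reference design for imbalanced phenotyping
cohorts: `floor(0.8 * P)` of the positives, matched by an equal seeded
undersample of negatives, form a balanced training set; the remaining
positives appear in **both** test sets — once paired with an equal number of
unused negatives (balanced test), and once paired with enough unused negatives
to bring positive prevalence closest to a 30% target (prevalence-matched
test). With 137 positives and 1789 negatives this yields 109+109 training
patients and 28+28 balanced-test patients. The closest-to-30% rule selects 65
unbalanced-test negatives (28/93 = 0.301); a design that fixes some other
count — 63 is a documented choice in prior work, giving 28/91 = 0.308 — can be
reproduced exactly via the `unbalanced_negatives` argument.

## The synthetic cohort generator

Clinical corpora with AD gold labels are protected health information and
cannot ship with a package, so `generate_cohort()` produces a synthetic
stand-in with the statistical structure the pipeline assumes. Each patient
draws a UKWP criterion profile uniformly from the profiles consistent with
their assigned gold label (16 of the 64 profiles are AD-positive), and the
profile is rendered into template sentences:

- itchy or dry skin surfaces as category 5; flexural history, visible
  flexural dermatitis and early-onset rash as category 4; an
  asthma-or-hay-fever history is realized per record as asthma (category 7)
  and/or hay fever (category 2), with asthma patients also carrying asthma
  medications (category 8);
- AD-positive patients carry AD-directed nonasthma medication mentions
  (category 6), an atopic-allergy comorbidity (category 3) with probability
  0.6 (0.15 for non-AD patients, reflecting background atopy), and a direct
  mention of the diagnosis (category 1) with probability 0.8 — direct
  mentions are deliberately not guaranteed, since in real notes they also
  occur in family-history or uncertain contexts;
- early onset is rendered as text ("Rash began before age 2") but is not a
  separate vector element;
- each document also receives keyword-free distractor sentences, and a small
  fraction (5%) of documents carry one two-category sentence, since a real
  sentence can evidence several indicators at once.

The noise model (`noise_config()`) controls: `miss_rate` (a true criterion
leaves no trace), `spurious_rate` (an inactive category receives a
non-affirmed mention), and the fractions of mentions rendered negated /
other-experiencer / hypothetical. One mention per active category is kept
affirmed whenever the three fractions sum below 1, so a true criterion stays
detectable; at zero noise every active category is affirmed somewhere and the
binary pipeline can recover gold labels exactly (category 6 is a perfect
correlate of the label in that idealized regime). Default document counts
(2–6 per patient) and distractor counts (1–4 per document) are deliberate
desk-scale choices: real AD charts average tens of documents per patient, but
nothing in the pipeline depends on the absolute volume, and the smaller
default keeps every stage convenient to iterate on.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: realistic clinical prose (telegraphic style,
misspellings, section headers, copy-forward duplication), out-of-lexicon
synonym variation, abbreviation ambiguity beyond the few cases encoded,
temporally evolving disease status, and any correlation structure between
note length and disease severity. Synthetic sentences come from a finite
template bank, so sentence classifiers face a far easier separation problem
than on hospital text; accuracies on synthetic data are upper bounds in kind,
not estimates of clinical performance.

## Numerical and design choices

**Sentence segmentation** is deliberately rule-based (split at `.`, `!`, `?`
followed by whitespace and a capital or digit, and at hard newlines, with a
protected-abbreviation list), making the behaviour portable and exactly
testable, where a toolkit segmenter would be version-dependent.

**Lexicons ship as editable text files** (`inst/extdata/lexicon/`): one file
per category, one case-insensitive, word-boundary-anchored phrase per line,
plus `modifiers.txt` (trigger, status, direction) and `terminators.txt`. The
defaults cover common synonyms per category; the bare abbreviation "AD" and
the token "hfa" are matched only in disambiguating contexts ("AD" disabled by
default, "hfa" only adjacent to a known inhaler brand), because both have
competing clinical meanings.

**Assertion scope** follows the standard ConText convention: a forward
trigger's scope runs from the trigger to the next terminator (`but`,
`however`, `;`, ...) or the sentence end; a backward trigger's scope runs
from the previous terminator (or sentence start) to the trigger. When scopes
overlap, precedence is negated > experiencer_other > hypothetical > affirmed.
Since all three non-affirmed statuses are treated identically downstream,
precedence affects only diagnostics, not patient vectors.

**The hashing embedding backend** is a seeded signed-hash bag-of-tokens
projection to 768 dimensions, L2-normalized. It is the package's
deterministic, download-free backend: keyword-bearing sentences from
different categories occupy near-orthogonal directions by construction, so
the MLP stage is exercised meaningfully without transformer weights. A
transformer backend (general-domain or clinical-domain checkpoint,
classification-position pooling by default, 512-token head truncation) shares
the same interface and raises a clear error directing users to the hashing
backend when no weights are available. Head truncation keeps the leading
tokens, which in generated fixtures retains the matched keyword.

**MLP training defaults.** Initialization is uniform with fan-in scaling,
drawn from the run seed; training is bitwise deterministic given the seed.
The minibatch size defaults to 16: with the fixed 10-epoch, lr 0.001,
momentum 0.9 recipe, the number of parameter updates per epoch is the only
remaining throughput knob, and at desk-scale dataset sizes (hundreds of
examples per class) batches of 32 leave the sparser categories visibly
under-trained while 16 trains all eight categories to convergence. Both are
available via `batch_size`.

**Sentence-dataset splits are grouped by patient** (all sentences of a
patient fall on one side) to avoid leakage between a classifier's training
and testing sentences; each side is then re-balanced by seeded undersampling.
Sentences matched to *no* category are excluded from negatives by default
(negatives are "sentences from the other categories"), with
`include_unmatched` available to widen the pool.

**Model selection** uses mean 5-fold CV accuracy with ties broken by grid
order, and default grids are intentionally small (cost for the SVM,
complexity for the trees, k for KNN, depth/rounds for boosting); grids are
plain lists and fully replaceable. AdaBoost is implemented in-package as
AdaBoost.M1 over `rpart` stumps; the stacking meta-learner is logistic
regression over out-of-fold base predictions.

**Seeds.** Every stochastic stage (profile sampling, rendering, undersampling,
fold assignment, weight initialization, shuffling) draws from a local RNG
seeded by deriving per-stage seeds from one master seed, so any stage can be
re-run in isolation and whole-pipeline runs are reproducible byte for byte.

## Scale used by the test suite

The shipped tests and the acceptance script run the full pipeline on
synthetic cohorts of 137/1789 patients (the reference composition) for the
end-to-end binary experiment, and on a 300/900 cohort to assemble 500-per-class
sentence datasets for all eight categories — sizes chosen so the whole suite
completes in a few minutes on a single core while still exercising every
stage at realistic class ratios.

## Known limitations

- The assertion rule set covers the three non-affirmed statuses the patient
  vector needs; it is not a full ConText implementation (no historical or
  temporal statuses).
- The hashing backend captures lexical overlap only; conclusions about
  transformer embedding quality cannot be drawn from it.
- Binary and probability modes coincide under thresholding only with perfect
  sentence classifiers; with trained classifiers the max operator compounds
  false positives as record length grows, which is precisely why the two
  modes are worth comparing.
- The UKWP-to-category mapping is configurable but the defaults embed
  clinical judgement (e.g. medication categories as label correlates) that a
  different deployment may wish to revisit.
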