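---
title: "Phenotyping stroke from radiology reports: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping stroke from radiology reports: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiologists record stroke findings in free-text CT/CTA/MRI/MRA reports.
Three binary facts buried in that text drive both research cohort
construction and clinical triage: whether an ischemic stroke is present,
whether it involves the middle-cerebral-artery (MCA) territory — the
location most relevant to thrombectomy — and whether it is acute
(roughly, within the last 7–10 days, or diffusion restriction without T2
prolongation on MRI). `strokenlp` implements a complete pipeline for
learning these labels from report text: preprocessing, three
featurization families, five classifier families, and a repeated-split
evaluation protocol, plus a synthetic report generator so every stage is
testable without protected health information.

## Preprocessing

Cleaning removes site-specific boilerplate (a configurable regex list;
header formats differ across institutions, so these are configuration,
not constants), strips separator runs such as `= = = = = =`, lowercases,
and replaces punctuation by *spaces* rather than deleting it — dictation
artifacts like `stroke.Impression` must not fuse words. Sentence
terminators survive until sentence splitting because the hierarchical
LSTM consumes sentences. Cleaning is idempotent.

A phrase lexicon then merges multi-word medical concepts into single
tokens (`middle cerebral artery` → `middlecerebralartery`), longest
match first. The shipped lexicon (~30 neurovascular phrases: arterial
anatomy, vascular territories, diffusion terminology, and the negation
frame `no evidence of`) is a starting point and user-extensible as a
two-column CSV; no published lexicon exists for this domain. Stop words
are retained deliberately — tf-idf, not a stop list, is the mechanism
for down-weighting them.

## Featurization

* **Bag of words** — absolute token frequencies over a vocabulary fitted
  on the *training* split only (`min_df` trims hapax noise).
* **tf-idf** — counts re-weighted by smoothed inverse document
  frequency, `idf(t) = ln((1+N)/(1+df(t))) + 1`. The smoothing keeps
  weights defined for tokens unseen at test time and floors every weight
  at the raw term frequency; a token present in every training document
  gets weight exactly 1. No length normalisation is applied by default
  (an L2 flag exists) since the choice is genuinely open.
* **Document embeddings** — the elementwise *sum* of the word vectors of
  in-vocabulary tokens; out-of-vocabulary tokens contribute nothing, and
  the representation is order-invariant.

## Training word embeddings

`train_glove()` fits vectors to the log of a sentence-bounded,
symmetric, harmonically weighted co-occurrence matrix (each pair at
distance *k* ≤ window adds 1/*k*) by AdaGrad on the weighted
least-squares objective with weighting `f(x) = (x/x_max)^0.75` capped at
1. Defaults — dimension 100, 50 epochs, window 10, learning rate 0.05 —
are the settings used for the neuroradiology embeddings this package's
protocol was built around; `x_max = 100` and the 0.75 exponent are the
method's canonical values. Same-token pairs are excluded from the
matrix, so the diagonal is zero. "Iterations" are read as epochs (one
shuffled pass over the nonzero entries), and windows do not cross
sentence boundaries by default; a `span_sentences` flag restores
document-level windows for corpora where sentence segmentation is
unreliable. Exported vectors are `w + w̃` (main plus context), the usual
small-accuracy-gain convention. Training is single-threaded and fully
seeded: identical seeds give bitwise-identical loss histories. That
costs speed at large corpus scale, but reproducibility outranks
throughput at the corpus sizes this package targets.

## Classifiers

Lasso logistic regression (glmnet backend), k-nearest neighbours
(Euclidean, vote-fraction probabilities, deterministic index tie-break),
CART (rpart; gini or entropy splits), random forest (randomForest, 200
trees; `type = "prob"` yields tree-vote fractions, i.e. multiples of
1/200), and a hierarchical LSTM. Features are standardised internally
(training statistics only) for the two scale-sensitive families, logreg
and k-NN.

Two numerical points deserve record. First, coordinate descent started
cold at a single small penalty need not converge, so each lasso fit runs
down a short geometric path from the analytically computed
`lambda_max` (the smallest penalty with an all-zero solution) to the
requested `lambda`. Second, the backend's `maxit`/`thresh` use different
units than the conventional optimizer-level `max_iter = 1000` /
`tol = 0.01` defaults recorded in the spec object: `thresh` is relative
to the null deviance, and `maxit` counts single coordinate passes. The
mapping used (`thresh = min(tol, 1e-7)`, `maxit = max_iter × 100`) is
never *looser* than the stated tolerance.

The recurrent model is a two-level LSTM: a word-level encoder maps each
sentence's embedded token sequence to its final hidden state (the
sentence vector); a sentence-level encoder maps the sentence-vector
sequence to a document vector; an affine + logistic head emits the
probability. Embedding rows are frozen (a flagged design choice: at
~1,000 labelled documents, fine-tuning 100-dimensional embeddings mostly
buys overfitting). Hidden widths 64/64, 20 epochs, batch 32 and Adam at
0.01 with global-norm clipping at 5 are desk-scale defaults, all
exposed. Initialisation is uniform (−0.08, 0.08) with forget-gate biases
at +1; all randomness derives from one seed, and the backward pass is
validated against finite differences in the test suite.

Hyperparameters are chosen by grid search with stratified 10-fold
cross-validation on the training side, selecting on mean validation AUC;
ties go to the simpler model (larger penalty, shallower tree, smaller
k). The k-NN grid is {5, 10, 15, 20} and tree depth/bucket parameters
range over 1–10.

## Evaluation protocol

Five seeded random 75/25 partitions; each side's prevalence is
stratified to within one sample of what the sizes allow. By default,
splits are grouped by patient so no patient's reports straddle train and
test — report-level splitting (available by flag) lets repeat imaging of
one patient leak across the boundary, which flatters test AUC. AUC is
computed in its rank (Mann–Whitney) form with ties credited ½, and the
cross-split confidence interval is the normal approximation
`mean ± 1.96·sd/√5` clipped to [0, 1] — percentile intervals over five
replicates are too unstable to be honest. Operating thresholds are
sensitivity-first: among thresholds achieving sensitivity ≥ 0.90 (read
as ≥, on the evaluated set, under the fixed decision rule `p ≥ t`), the
one maximising specificity, largest threshold on ties; if the floor is
unattainable the maximal-sensitivity threshold is returned and the
fallback logged. Calibration uses the fixed bins [0, 0.1], (0.1, 0.2],
…, (0.9, 1]; empty bins are reported with a missing rate, never zero.
Precision with no predicted positives is likewise missing, not zero.
Paired models are compared with the McNemar discordant-count test,
two-sided, χ² = (b−c)²/(b+c) without continuity correction by default
(the corrected form, clamped at zero, is a flag); b + c = 0 degenerates
to χ² = 0, p = 1.

The five "bootstrapped" splits are implemented as five independent random
partitions (not resampling with replacement), matching the protocol's
description of repeatedly splitting the data; an external-validation
mode instead evaluates each split's trained model on the entire external
cohort.

## The synthetic generator

`generate_reports()` emulates the labelled cohort the protocol was
designed around: 1,359 reports, stroke prevalence 925/1359, MCA
involvement 350/925 of strokes, acute findings 522/925, roughly
two-thirds CT/CTA, ~4.6 reports per patient. Reports are assembled from
templates — exam header (sometimes with boilerplate and separator lines,
so cleaning has real work), history, findings, impression — with
modality-appropriate acute language (restricted diffusion on MRI;
hypodensity with loss of grey-white differentiation on CT).

The templates deliberately encode the documented hard cases:

* negated stroke phrases ("no evidence of acute infarct") in half of the
  stroke-negative reports (`negation_rate = 0.5`);
* chronic-infarct language (encephalomalacia, lacunar infarcts) that is
  stroke-positive but acuity-negative;
* small-vessel / microvascular "ischemic changes" in negatives, and
  prior-scan re-descriptions ("redemonstration of the acute infarct seen
  on the prior examination") that keep affirmative acute wording in
  non-acute reports (`distractor_rate = 0.3`);
* "subacute" wording used identically for strokes adjudicated acute or
  chronic, in half of stroke reports — subacute is a relative term in
  dictation, and this is what makes acuity intrinsically the hardest of
  the three tasks, reproducing the ordering seen on real cohorts;
* per-label flips at `label_noise = 0.03`, emulating the ~97% adjudicated
  inter-rater agreement of expert labelling (noise is applied after the
  `mca ⇒ stroke`, `acute ⇒ stroke` invariants, so noisy labels may
  violate them, as real labels can).

What the generator does **not** emulate: within-patient correlation of
findings across serial scans, site-specific template drift, dictation
typos and OCR noise, rare stroke mimics, and the long-tailed vocabulary
of real radiology. Passing tests on synthetic data therefore demonstrate
that the machinery is correct and that the pipeline recovers planted
signal under realistic nuisance structure — not that any particular AUC
will transfer to a hospital corpus.

`generate_embedding_corpus()` plants synonym pairs in identical, pair-
specific sentence frames over a Zipf background; a trainer that captures
co-occurrence structure must assign near-parallel vectors within a pair
and visibly lower similarity across pairs. This is the embedding
trainer's acceptance property.

## Problem sizes used in the checks

The shipped checks run the full protocol at the cohort's own scale
(1,359 reports, five 75/25 splits, 10-fold tuning) for the bag-of-words
and document-embedding pipelines; embedding-recovery checks use 20
seeded corpora of 150 documents; the recurrent model's separation check
uses 800 training and 200 test documents. These sizes were chosen so the
whole suite runs comfortably on a single CPU while keeping every
statistical check at a scale where its expected behaviour is
unambiguous.

## Known limitations

Proprietary optimal-classification-tree learners reported alongside
these methods elsewhere are out of scope, as is reproducing any
real-cohort AUC (the underlying reports are PHI). The released reference
embedding file cannot be regenerated value-for-value because its
training corpus is not distributable; the trainer here reproduces the
*method*, with its quality property checked on planted-structure
corpora. k-NN materialises dense distance computations and is not meant
for very wide vocabularies; the LSTM is single-threaded by design.
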