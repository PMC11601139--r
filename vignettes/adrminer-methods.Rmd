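---
title: "Methods: mining and classifying adverse-drug-reaction posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and classifying adverse-drug-reaction posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrminer)
```

## The problem and the model

Drug-targeted social-media collections contain three kinds of posts: posts
that describe an adverse drug reaction (ADR) the author experienced, posts
that mention a drug and its documented side effects without any personal
reaction (questions, product chatter, relayed warnings), and posts that are
simply off topic. `adrminer` implements a staged pipeline that first uses
*term-level* evidence to narrow the corpus and then a *sequence-level*
classifier to make the final call:

1. **Tagging.** Posts are normalized (URL and control-character removal,
   whitespace collapse, case folding — normalization is idempotent) and
   tokenized. Drug and ADR lexicon hits are tagged `surface_id_class`
   (e.g. `blisters_153_ADR`); stop words are dropped. Tagging is
   deterministic: the same lexicons and text always produce the same tags.
2. **Association filtering.** Each post's distinct tagged terms form a
   transaction. For every drug $d$ and ADR term $a$,
   $\mathrm{supp}(d\to a) = n_{da}/N$,
   $\mathrm{conf}(d \to a) = n_{da}/n_d$, and
   $\mathrm{lift} = \mathrm{conf} / (n_a/N)$.
   Rules with support $\ge$ 0.01 and confidence $\ge$ 0.6 (defaults) define
   the *known co-occurrence pairs*; posts containing both members of at
   least one rule survive. Lift is reported for inspection but does not
   gate filtering, because the screening decision is defined on support and
   confidence only.
3. **Embedding.** Skip-gram word2vec with negative sampling is trained on
   the filtered posts (not the full corpus: the embedding should reflect
   the vocabulary distribution the classifier will see). Tagged terms are
   single vocabulary items.
4. **Classification.** Posts are frequency-encoded (index 0 = padding,
   1 = out-of-vocabulary, then descending corpus frequency with
   lexicographic tie-breaks), left-padded / tail-truncated to a fixed
   length, split 7:3 with label stratification, and classified by a
   many-to-one bidirectional LSTM whose two final hidden states are
   concatenated into a single sigmoid unit, trained with binary
   cross-entropy and Adam.
5. **Evaluation.** Confusion matrix at the decision threshold, ADR-class
   precision/recall/F1, a descending threshold sweep for the ROC curve with
   trapezoidal AUC, and chance-corrected annotator agreement (Cohen's and
   Fleiss' kappa).

The positive class is always ADR = 1; a non-ADR post is 0.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_support` | 0.01 | fraction of transactions | screening threshold for pair significance; low because consumer corpora mention any single reaction rarely |
| `min_confidence` | 0.6 | fraction | conditional rate of the ADR given the drug required to call a pair "known" |
| embedding `dim` | 300 | — | the conventional word2vec dimensionality for this task |
| embedding `window` / `min_count` / `epochs` / `negative` | 5 / 1 / 5 / 5 | tokens / count / passes / samples | common word2vec practice; only mode (skip-gram) and dimension are task-prescribed, the rest are exposed in the run config |
| `hidden_units` | 256 | per direction | headline Bi-LSTM size |
| `learning_rate`, `batch_size`, `epochs` | 0.001, 64, 50 | — | headline Adam settings |
| `threshold` | 0.5 | score | default binary decision point; the ROC sweep varies it over [0, 1] |
| `split_ratio` | 0.7 | fraction | 7:3 train/test convention |

## Numerical and design choices

* **Tokenization is pluggable.** Language-specific morphological analysis
  (spacing correction, morpheme segmentation) is out of scope; the default
  tokenizer is a unicode word-boundary split plus greedy longest-match
  merging of adjacent tokens into known multiword lexicon surfaces. Any
  function returning `(surface, start, end)` spans (0-based, half-open, on
  the normalized string) can replace it, which is where a Korean morpheme
  analyzer would slot in.
* **Lexicon collisions.** A surface in both the drug and ADR lexicons is
  tagged as drug (the drug mention anchors the rule antecedent) with a
  warning; an ADR/stop-word overlap is a validation error. Both policies
  are implementation decisions — the source methodology does not state a
  collision policy.
* **Rules are single-antecedent, single-consequent.** Only drug → ADR word
  pairs are reported in this methodology; general itemsets add nothing to
  the filtering decision. Thresholds are applied corpus-wide. Rule order is
  confidence desc, support desc, then lexicographic — fully deterministic.
* **Empty posts.** Posts with no tokens after stop-word removal are
  excluded and counted in the run report; the original collection's
  preprocessing shrinkage is not otherwise reproducible, so exclusions are
  made explicit rather than emulated.
* **Sequence masking and initialization.** With left padding, the backward
  direction of an unmasked Bi-LSTM would end every sequence by running
  through dozens of padding steps, decaying the signal it carried; the
  recurrent cells therefore carry state through padding positions unchanged
  (the `mask_zero` semantics of mainstream deep-learning toolkits). The
  LSTM forget-gate bias is initialized to 1 and the padding row of the
  embedding matrix is held at zero and never updated. All gradients
  (LSTM, GRU, convolution front end, embedding) are validated against
  central finite differences at 1e-4 relative tolerance in the test suite.
* **Embedding vectors are the mean of the input and output matrices.** The
  input matrix alone encodes paradigmatic similarity (words with similar
  contexts), but the similarity queries this pipeline needs are
  syntagmatic — a drug should be near the reactions it co-occurs with.
  Averaging the two matrices (a standard word2vec variant) mixes the
  first-order association into the cosine geometry; with input vectors
  alone, habitual co-occurrence is *not* reflected in cosine similarity.
* **Classifier OOV policy.** Tokens absent from the embedding vocabulary
  map to a reserved trainable index; word2vec initialization fills only the
  overlapping vocabulary rows and is fine-tuned by default
  (`freeze_embeddings = FALSE`).
* **CNN–Bi-LSTM variant.** The named architecture is underspecified in the
  source methodology; this package interprets it as one width-3
  same-padded 1-D convolution (128 filters, ReLU), width-2 max pooling,
  then the Bi-LSTM. GRU means a bidirectional GRU under the identical
  train/predict contract.
* **Early stopping** (patience 5 on a 10 % validation split carved from the
  training set) exists but is off for the headline configuration; it is
  described only for the model-comparison experiments.
* **Stratified split.** The 7:3 split stratifies by label with
  largest-remainder allocation, so the train size equals `round(0.7 N)`
  exactly and both splits preserve the class balance within one post. Plain
  random splitting could lose the minority class entirely at small n.
* **Degenerate inputs.** Undefined metric ratios (zero denominators) are
  `NA` with a warning, never silently 0. AUC on a single-class truth vector
  is an error. `cohens_kappa` returns 1 when both raters agree perfectly
  with degenerate marginals. `epochs = 0` yields a scoreable model flagged
  untrained.
* **Determinism.** Every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from one master seed. Two runs with the same
  config produce identical reports apart from timings.

## What the synthetic generator emulates — and what it does not

`generate()` produces a corpus whose *statistics* mirror a drug-targeted,
manually labeled pharmacovigilance collection:

* ADR prevalence defaults to 42.4 % (the main labeled set's composition;
  the `geworin_like` preset uses 27.96 % of 236 posts, the harder
  extra-drug balance). Labels are assigned by exact count at random
  positions, so the empirical prevalence is always within rounding of the
  target.
* Every true ADR post contains one drug mention, that drug's planted ADR
  term(s) per the pair matrix, and `1 + Poisson(0.8)` additional symptom
  terms from the wider ADR vocabulary — the experiential signal.
* Non-ADR posts are, with probability 0.7, *incidental mentions*: the drug
  plus one of its known ADR words (people discussing documented side
  effects they did not experience). These survive association filtering, so
  the filtered subset is roughly balanced rather than trivially pure — the
  defining property of the emulated labeled set, which was only ~42 % true
  ADR posts despite every post containing a significant pair. With
  probability 0.25 a non-ADR post mentions the drug alone; otherwise it is
  drug-free chatter. The two rates were set from that composition
  arithmetic (they are the package's own extension of the generator
  contract, documented as such).
* Two annotator label vectors are drawn independently around the truth,
  with the agreement parameter calibrated analytically
  (`kappa_target_agreement()`) so the expected Cohen's kappa matches a
  target reliability (0.8 by default).
* Label noise, when enabled, is applied after pair planting, so the truth
  table stays exact and oracle checks remain possible.

The generator's "text" is space-delimited ASCII-safe tokens (a Hangul mode
exists to exercise unicode handling); it does **not** emulate natural
language: no grammar, no negation, no misspellings, no channel-specific
formatting, no near-duplicate posts. Consequently a green end-to-end test
establishes that the pipeline's stages compose correctly and can recover a
strong planted signal at realistic sample sizes — it does not establish
classification performance on real consumer text, which depends on
morphological analysis and labeling quality outside this package's scope.
The closure tests deliberately use reduced layer sizes and epochs
(documented in the test files) to stay desk-scale; statistical thresholds
are never loosened to compensate.

## Known limitations

* The tokenizer contract replaces Korean morphological analysis; results on
  agglutinative text will depend on the plugged-in tokenizer.
* Lexicon curation (terminology mapping from registries and side-effect
  databases) is out of scope; lexicons are inputs.
* No deduplication across channels, no disproportionality statistics
  (PRR/ROR), no confidence intervals on AUC, no class-weighting for
  imbalance, no pretrained-transformer baseline.
* The native deep-learning implementation is single-threaded R matrix code:
  correct (gradient-checked) and adequate for corpora of a few thousand
  posts, but not a performance substitute for a GPU toolkit at web scale.
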