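# adrminer

Detecting adverse-drug-reaction (ADR) posts in consumer social-media text.

Post-marketing drug surveillance increasingly looks beyond spontaneous-report
registries to what patients write online. `adrminer` implements, as a tested
and reusable R pipeline, a lexicon-plus-deep-learning approach for finding
the posts in a drug-targeted social-media collection that describe an actual
adverse reaction (as opposed to merely mentioning a drug or its documented
side effects):

1. **Lexicon tagging** — drug brand names, ADR terms and stop words are
   loaded from TSV lexicons; posts are normalized, tokenized (pluggable
   tokenizer with greedy longest-match for multiword terms like
   *muscle pain*) and tagged, rendering matches as `surface_id_class`
   tokens such as `blisters_153_ADR`.
2. **Association filtering** — each post's tagged terms form a
   market-basket transaction; single-antecedent drug → ADR rules are mined
   with the standard definitions

   support(d → a) = n(d, a)/N,  confidence = n(d, a)/n(d),  lift = confidence / (n(a)/N)

   and posts containing both members of a significant pair
   (support ≥ 0.01, confidence ≥ 0.6 by default) are kept as candidate ADR
   posts.
3. **Skip-gram embeddings** — word2vec-style vectors (skip-gram with
   negative sampling, 300 dimensions by default) are trained natively on the
   filtered posts and expose cosine-similarity and nearest-neighbour
   queries; they also initialize the classifier's embedding layer.
4. **Bi-LSTM classification** — posts are frequency-encoded as left-padded
   integer sequences and classified by a many-to-one bidirectional LSTM
   (256 hidden units per direction, sigmoid output, binary cross-entropy,
   Adam at learning rate 0.001, batch 64, 50 epochs, 7:3 stratified split,
   decision threshold 0.5). GRU and CNN–Bi-LSTM variants share the same
   contract. The recurrent cells, masking, backpropagation-through-time and
   Adam are implemented in base-R matrix code and verified against
   finite-difference gradients.
5. **Evaluation** — confusion matrices, precision/recall/F1 for the ADR
   class, ROC threshold sweeps with trapezoidal AUC (checked against the
   Mann–Whitney rank statistic), and Cohen's/Fleiss' kappa for annotator
   reliability.

Because real labeled pharmacovigilance corpora are rarely distributable, the
package ships a first-class synthetic-corpus generator (`generate()`,
`preset_config()`) that emulates the statistical structure of such a
collection — 42.4 % ADR prevalence, planted drug–ADR pairs, incidental
known-ADR mentions in non-ADR posts, paired annotators calibrated to
κ ≈ 0.8 — so every stage is testable end to end with no external data.

## Worked example

```r
library(adrminer)

rep <- run_pipeline(list(
  preset = "ketoprofen_like",   # 576-post-style world, here scaled to 600
  n_posts = 600, seed = 7,
  embedding_dim = 32, embedding_epochs = 2,   # desk-scale settings
  hidden_units = 24, epochs = 20, learning_rate = 0.005, batch_size = 32,
  out_dir = "demo_run"))
print(rep)
#> <adr_run_report>
#>   posts read       600 (0 excluded empty)
#>   transactions     578, rules 9
#>   filter           502 retained / 98 dropped
#>   split            351 train / 151 test
#>   test accuracy    0.993  (AUC 1.000)
```

Reading the report: all 9 planted drug → ADR pairs were recovered by rule
mining; 502 of 600 posts contained a significant pair and were retained;
the Bi-LSTM, trained on 351 labeled posts, classified the 151 held-out
posts with 99 % accuracy and AUC 1.00 (the synthetic world's planted signal
is strong by design — see the methods vignette for what this does and does
not establish). The simulated annotator pair for this run agreed at
Cohen's κ = 0.786, near the 0.8 calibration target.

The same stages are available piecemeal (`read_corpus()`, `load_lexicon()`,
`preprocess_corpus()`, `mine_rules()`, `filter_posts()`,
`train_embeddings()`, `train_classifier()`, `evaluate_scores()`,
`cohens_kappa()`, ...) and as a CLI:

```sh
inst/cli/adrminer simulate --preset ketoprofen_like --seed 7 --out sim/
inst/cli/adrminer preprocess --corpus sim/corpus.jsonl \
  --drug-lex sim/drug_lexicon.tsv --adr-lex sim/adr_lexicon.tsv \
  --stop-lex sim/stop_lexicon.tsv --out tokens.jsonl
inst/cli/adrminer mine --tokens tokens.jsonl --rules rules.tsv
```

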