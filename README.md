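# metaug

Targeted paraphrase augmentation for longitudinal radiology-report
classification.

## What problem this solves

Detecting organ-specific metastatic disease from the free-text
*impression* sections of serial radiology reports is label-scarce and
class-imbalanced, and the decisive context is often in a patient's
earlier exams rather than the current report. `metaug` is an R toolkit
for studying two remedies together:

1. **Generative data augmentation.** Training impressions are
   paraphrased *N* times and recombined into whole synthetic patient
   timelines. Besides *vanilla* augmentation (paraphrase everything),
   three *targeted* strategies paraphrase only a chosen subset:
   reports with ≥ 20 words (**length filtering**), reports misclassified
   by held-out-fold models (**KF-MF**, k-fold misclassification
   mining), and reports of minority-class patients with balancing
   replication (**minority**). Targeted runs are budget-matched: their
   continuation epochs are scaled so `epochs × training patients`
   equals the vanilla run's budget.
2. **Patient-level hierarchical classification.** Each report is
   embedded (`e_i = M(r_i) ∈ R^d`), down-projected to 128, passed
   through a one-directional LSTM and causally masked multi-head
   attention, and a per-position head outputs `ŷ_j = P(metastasis at
   exam j)` for all positions in one pass — predictions at time *j*
   depend only on exams `i ≤ j`.

The encoder ships in three forms: a deterministic hashed n-gram
encoder, a small in-repo transformer carrying the
parameter-efficient fine-tuning contracts (**LoRA** on query/value
projections with zero-initialized `B`, and **deep prefix-tuning** with
per-layer trainable key/value prompts), and an adapter slot for an
external pretrained model. Because the motivating clinical corpora are
access-restricted, the package also ships a seeded synthetic-corpus
generator reproducing their statistical shape (per-organ positive rates
0.31/0.16/0.07, ~9 reports per patient, timelines of 1–30 reports,
persistent labels, controllable lexical cues, impression lengths
straddling the 20-word threshold), so the whole pipeline runs and is
tested offline.

## Worked example

```r
library(metaug)

# 1. a liver-like corpus: 60 patients, report-level positive rate 0.31
corpus <- generate_corpus(generator_config(60, organ = "liver", seed = 7)) |>
  split_by_patient(c(train = 0.6, validation = 0.2, test = 0.2), seed = 1)
corpus_summary(corpus)
#> # A tibble: 1 × 7
#>   n_patients n_reports n_positive positive_rate words_q25 words_median words_q75
#>        <int>     <int>      <int>         <dbl>     <dbl>        <int>     <dbl>
#> 1         60       529        156         0.295        19           30        42

train_c <- dplyr::filter(corpus, split == "train")
val_c   <- dplyr::filter(corpus, split == "validation")
test_c  <- dplyr::filter(corpus, split == "test")

# 2. train the hierarchical classifier on original data
enc <- encoder_config(kind = "hashed_ngram", dim = 256)
agg <- aggregator_config(input_dim = 256, projected_dim = 32,
                         recurrent_hidden = 32, attention_heads = 2)
fit <- build_model(enc, agg, seed = 1) |>
  train(train_c, val_c, training_config(max_epochs = 40, patience = 12, seed = 1))
glance(fit)
#> # A tibble: 1 × 4
#>   n_epochs best_epoch best_validation_f1 final_train_loss
#>      <int>      <int>              <dbl>            <dbl>
#> 1       28         16              0.857          0.00557

# 3. vanilla augmentation: N = 10 paraphrases, maximum-use composition,
#    10 continuation epochs
sel <- select_vanilla(train_c)
variants <- generate_variant_sets(train_c, sel,
                                  paraphrase_config(n_variants = 10, seed = 1))
aug <- assemble_augmented_dataset(train_c,
                                  compose_corpus(train_c, variants, seed = 1))
fit_da <- continue_on_augmented(fit, aug, val_c, epochs = 10,
                                training_config(seed = 1))

binary_f1(predict_corpus(fit$model, test_c))     # no-DA baseline
#> [1] 0.9014085
binary_f1(predict_corpus(fit_da$model, test_c))  # with augmentation
#> [1] 0.9014085

# 4. how much history matters: full timeline vs a one-year window
binary_f1(evaluate_with_window(fit_da$model, test_c, window_years = 1))
#> [1] 0.9014085

# 5. diversity of the paraphrases (lower self-BLEU = more diverse)
diversity_report(variants, train_c)
#> # A tibble: 1 × 6
#>   self_bleu_single self_bleu_multi cosine_similarity n_max n_sets n_variants
#>              <dbl>           <dbl>             <dbl> <int>  <int>      <int>
#> 1            0.734           0.941             0.909     5    302       3020
```

Reading the numbers: with only 36 training patients the augmented
model matches the already-converged baseline (the best-validation
checkpoint rule never accepts a worse model), and at this timeline
density a one-year window loses nothing; the history and augmentation
gaps open up at the 450-patient reference scale (see below). The
variants are lexically diverse relative to their sources (self-BLEU
0.73) while staying semantically close (cosine 0.91) and much more
self-similar within a pool (0.94) — the single < multi ordering
expected of a paraphraser that preserves meaning-critical phrases.

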