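---
title: "Methods: targeted paraphrase augmentation for longitudinal report classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted paraphrase augmentation for longitudinal report classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaug)
```

## The problem and the model

Annotating metastatic disease per organ from radiology reports is a
report-level binary classification task in which labels are scarce,
classes are imbalanced (per-organ positive rates in real registries run
from roughly 7% to 31%), and the decisive context is often *not* in the
current report but in the patient's earlier exams. `metaug` implements a
study pipeline around two ideas.

**Patient-level hierarchical classification.** A patient is an ordered
timeline \(R = (r_1, \dots, r_l)\), \(l \in [1, 30]\), with binary labels
\(Y^\* = (y^\*_1, \dots, y^\*_l)\). Each report is embedded by a text
encoder, \(e_i = M(r_i) \in \mathbb{R}^d\); the sequence is
down-projected to 128 dimensions, passed through a one-directional LSTM,
then through multi-head attention under a causal mask (position \(j\)
attends only to \(i \le j\)), and a per-position linear head with a
logistic link yields \(\hat y_j = P(\text{metastasis at exam } j)\). The
architecture computes all \(l\) outputs in one pass, and causality is
structural: a suffix perturbation cannot change any earlier prediction
(the test suite asserts bit-identity).

**Targeted generative augmentation.** Training impressions are
paraphrased \(N\) times (default \(N = 10\)) and the variants are
recombined into whole synthetic patients. "Vanilla" augmentation
paraphrases every training report; the targeted strategies paraphrase a
subset:

- *length filtering* keeps reports with at least 20 whitespace-delimited
  words (inclusive boundary — the simplest reading of a "minimum");
- *k-fold misclassification mining (KF-MF)* partitions training patients
  into \(k = 5\) folds, trains a fold model for 20 epochs on the
  complement, and selects every held-out report whose thresholded
  prediction disagrees with its label;
- *minority-class selection* takes all reports of patients whose
  positive fraction is ≥ 0.5 and replicates those patients
  \(\max(0, \mathrm{round}(n_-/\max(1, n_+)) - 1)\) times, approximately
  balancing report-level classes.

## Synthetic corpus generator

The real corpora for this task are access-restricted, so the generator
is a first-class module, not a test fixture. It emulates the statistics
that matter to the pipeline:

- organ-specific report-level positive rates (liver 0.31, lung 0.16,
  adrenal 0.07 by default);
- timeline lengths \(1 + \mathrm{Poisson}(\bar l - 1)\) truncated at 30,
  with \(\bar l = 9\);
- exam dates: first exam uniform in a 10-year window, i.i.d. exponential
  gaps with mean \(1/3\) year (so a one-year history window holds about
  three exams);
- a two-state label chain: positive labels persist with probability 0.9;
  the 0→1 rate is solved from \(\pi(1-q)/(1-\pi)\) so that the
  *stationary* report-level rate equals the configured positive rate at
  every position, which is the only quantity such registries publish;
- impression text assembled from a lead "label sentence" plus neutral
  filler sentences. With probability `cue_strength` (default 0.7) the
  lead sentence carries an organ-specific metastasis-affirming or
  benign/negating phrase from two disjoint, versioned phrase banks;
  otherwise it is uninformative. Filler sentences include millimetre
  measurements so digit preservation is exercised, and sentence counts
  are drawn so word counts span ~6–120, populating both sides of the
  20-word filter threshold.

Persistence 0.9 and cue strength 0.7 are acknowledged fabrications
chosen once for testability — real institutions do not publish those
statistics. What passing tests show is therefore that the *machinery*
(selection, composition, budget matching, causal modelling) behaves as
specified under a controllable signal; they say nothing about absolute
F1 on clinical text, which also exhibits template structure, negation
scope, and inter-annotator noise the generator does not model.

## Paraphrase engine

The production interface is a prompt builder plus an adapter contract
(text in, list of texts out) for an external instruction-tuned LLM;
decoding metadata (temperature 0.3, repetition penalty 1.15) is recorded
in the config. No network code ships. The prompt has four parts —
background, task description, demonstration original, demonstration
paraphrase — joined with escaped section markers so that
`parse_prompt(build_prompt(...))` is an exact inverse even when the text
contains a marker. The demonstration pair is package fixture prose.

For offline work the deterministic rule-based engine stands in: cue-bank
phrases are masked (so the label signal is copied verbatim), non-cue
content words are substituted from a fixed synonym lexicon, and non-cue
sentences are permuted. The lexicon contains no digits and no cue
vocabulary, so measurements survive and labels cannot flip. Variant
\(k\) is a pure function of `(impression, seed, k)`. Below 20 words the
substitution rate collapses (0.1 vs 0.6), reproducing the phenomenon
that motivates length filtering: short sources yield near-duplicate
variants. On generated corpora, multi-reference self-BLEU of variants of
long (≥ 40 word) sources is measurably lower than that of short
(< 20 word) sources.

## Composing synthetic patients

Let \(l_{i,\mathrm{syn}}\) be the variant count at position \(i\) and
\(m = \max_i l_{i,\mathrm{syn}}\). The composer emits \(m\) synthetic
patients; slot \(i\) of synthetic patient \(j\) holds

1. the \(j\)-th element of a seeded permutation of variant set \(i\)
   when \(j \le l_{i,\mathrm{syn}}\),
2. a seeded draw with replacement from set \(i\) when
   \(1 \le l_{i,\mathrm{syn}} < j\),
3. a fresh copy of the original report when \(l_{i,\mathrm{syn}} = 0\).

Every variant is used at least once (maximum use), labels/dates/positions
are copied from the source, and randomness is keyed by
`(seed, patient_id, position)` so composition is reproducible and
order-independent. The exact matching rule when variant counts differ
across positions is underdetermined in the literature; this fill rule is
the package's documented construction. Synthetic patients inherit the
source patient's training membership and can never reach validation or
test splits (enforced with an integrity error).

For the minority strategy, replicas (rather than maximum-use
composition) are the mechanism: replica \(r\) takes variant
\(((r-1) \bmod l_i)+1\) at each position, falling back to the original
text, so replicas reuse distinct paraphrases round-robin.

## Encoder and parameter-efficient fine-tuning

A pretrained clinical encoder is out of scope offline, so the PEFT
*mechanics* — the actual contribution surface — are carried by a small
in-repo transformer: hashed token + learned positional embeddings,
`layers` blocks of multi-head self-attention and ReLU feed-forward with
residual connections, mean pooling, and a linear map to \(d\). At this
depth and width normalization layers are unnecessary; initialization is
\(\mathcal N(0, 0.08^2)\) and training runs in standard precision. Head
truncation at `max_tokens` is used (impressions are short); the
findings-plus-impression input mode concatenates findings first with a
`[SEP]` marker. A trainable-free hashed n-gram encoder (unigrams +
bigrams, FNV-1a hashing trick, L2-normalized) provides a fast
deterministic backend, and an external-adapter slot accepts a real
pretrained encoder without changing downstream contracts.

- **LoRA** adds \(W' = W + s\,A B\) to the query and value projections
  (the combination reported to matter most), with \(A\) random and \(B\)
  zero-initialized so attachment is bit-exact identity; only \(A, B\)
  receive gradients; `merge_lora()` folds the update into the weights
  with outputs equal to the adapted encoder within 1e-5 relative, and a
  second merge is a state error.
- **Deep prefix-tuning** (P-tuning v2 style) prepends `prompt_length`
  trainable key/value rows in *every* attention layer, optionally
  initialized from vocabulary embeddings; trainable count is
  `layers × prompt_length × 2 × width`.

All gradients — full fine-tuning, LoRA factors, prefixes, and the
aggregator — are analytic backpropagation written in base-R linear
algebra and are verified against central finite differences (worst
absolute error below 1e-6 at probe scale) in the test suite.

## Training protocol

Mean binary cross-entropy over all report positions is minimized with
Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) and a half-cosine learning-rate
schedule, default peak 0.005. Defaults follow the protocol the study
design prescribes: up to 1,000 epochs with early stopping at 200 epochs
of patience on validation F1, checkpoint selection by best validation
F1. Loss is averaged per report position (labels are per report), and
each optimizer step consumes one patient by default (`batch_size`
accumulates). Training is a pure function of the seed: patient order,
initialization, and every stochastic choice run on keyed substreams.

Augmentation never retrains from scratch: `continue_on_augmented()`
resumes from the base model for exactly `epochs` epochs on original +
synthetic patients, again keeping the best-validation-F1 checkpoint;
the starting model is included as an epoch-0 candidate since it was
already validation-selected. Vanilla continuation uses 10 epochs at
\(N = 10\); targeted strategies use
`budget_matched_epochs() = round(base · (n_orig + n_syn_vanilla) /
(n_orig + n_syn_targeted))`, floored at 1, interpreting "computation
budget" as epochs × training patients (the interpretation is the
package's own; the literature states the goal, not the formula).
Class imbalance without augmentation can be handled by
`minority_upsampling`, which duplicates minority patients in the epoch
ordering by the same balancing factor as the minority strategy.

## Evaluation conventions

- **F1** is positive-class F1 pooled over all report positions across
  patients, threshold 0.5; the degenerate no-positives case is defined
  as 0 with a warning flag.
- **Multi-seed sweeps** rerun the full pipeline per seed on fixed splits
  and report mean ± sd and best.
- **History windows** are measured backwards from the target report's
  date in calendar years of 365.25 days; the target is always retained,
  and truncation is applied at evaluation time only. The prediction for
  the target is read at the truncated sequence's last position.
- **Self-BLEU** uses lowercased, punctuation-split tokens, modified
  n-gram precision with reference clipping, uniform weights over orders
  1..5, and a brevity penalty against the closest reference length
  (ties to the shorter). Orders where the candidate has no n-grams are
  skipped so identical texts score exactly 1 at any length. Zero
  precision yields 0 by default; an optional flag floors zero
  precisions at 1e-4. Single-reference mode scores a variant against
  its source; multi-reference mode against the other variants of the
  same source (sets of size one are skipped).
- **Cosine similarity** uses a pluggable embedder, defaulting to the
  deterministic hashed encoder so no checkpoint is required.

## Desk-scale experiment sizes

The package's reference experiment (`da_benchmark()`, also what
`scripts/acceptance.R` reruns) uses a liver-like corpus of 450 patients
(200 train / 100 validation / 150 test, positive rate 0.31, cue
strength 0.7, persistence 0.9), the hashed encoder at \(d = 256\), an
aggregator at projected/hidden width 32 with 2 heads, base training
capped at 40 epochs with patience 12, \(N = 10\) paraphrase variants,
10 continuation epochs, and 5 seeds. These sizes are the package's
choices for a single-CPU reference run; the defaults on the public
functions remain the full-scale protocol values. Observed behaviour at
this scale: vanilla augmentation matches or improves the no-DA baseline,
and test F1 orders full history ≥ one-year window ≥ single-report
baseline — the directional signatures the architecture is built for.

## Known limitations

- Generated prose is template-assembled; it exercises lexical signal,
  lengths, digits and timing, not clinical language understanding.
- The rule-based paraphraser cannot model LLM hallucination or factual
  drift, so post-generation filtering is (deliberately) out of scope.
- The tiny transformer demonstrates PEFT mechanics; its absolute
  accuracy is irrelevant and untested by design.
- Half-precision kernels, distributed training, and hyperparameter
  search are out of scope.
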