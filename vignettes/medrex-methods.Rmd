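---
title: "Relation extraction with a pre-trained encoder and a 1d-CNN head: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation extraction with a pre-trained encoder and a 1d-CNN head: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(medrex)
```

## The problem

Biomedical corpora annotate relations between normalized entities — a
chemical and the disease it induces in a PubTator abstract, an herb and a
syndrome in a traditional-medicine literature table, an event and a time
expression in a clinical note. The corpora are small (hundreds to a few
thousand labeled pairs per category), far below what a deep classifier
trained from scratch needs. `medrex` implements the remedy this package is
built around: pre-train a bidirectional transformer encoder on unlabeled
text with masked-token and next-sentence objectives, then fine-tune it for
relation classification under a multi-filter one-dimensional CNN head, so
that the linguistic knowledge acquired from unstructured text substitutes
for labels.

Everything here runs at desk scale on one CPU: the encoder geometry, the
corpus sizes and the training schedules are miniature, and a synthetic
corpus generator supplies data whose structure the method's assumptions
match by construction. The package is the full pipeline — corpus IO, sample
generation, WordPiece tokenization, encoder pre-training, fine-tuning,
evaluation — with the numerical core (forward passes, hand-derived
backpropagation, Adam) written in plain R matrix algebra.

## Classification units and sample generation

A classification instance is a *sentence pair*: sentence A is the two
entity names joined by a space (`"cocaine myocardial infarction"`),
sentence B is the context the pair co-occurred in (title + single space +
abstract). A "sentence" is a span of text, not a linguistic sentence.

For abstract-level corpora where only positive pairs are annotated,
`make_positive_samples()` labels every annotated pair `"1"` and
`make_negative_samples()` draws unannotated Chemical×Disease concept pairs
from the same document uniformly without replacement, labeled `"0"`, at a
1:1 ratio by default so the trained model is balanced. Design choices the
annotation format leaves open:

* *Which surface form names a concept*: the first mention in document
  order, lowercased for the uncased tokenizer. Concepts with several
  distinct surfaces are an ambiguity the format does not resolve; first
  mention is deterministic and matches the worked example.
* *Sampling scope*: negatives are drawn per document, not corpus-wide, so
  each document contributes a locally balanced set (the worked example's
  arithmetic — two negatives from a three-pair pool — only makes sense per
  document).
* *Undirected relations* (chemical-disease, herb-disease) are canonicalized
  with the identifier pair unordered before deduplication; directed
  relations (temporal links) are never reordered.

Instance-level corpora (the tab-delimited herb/formula tables) are already
labeled; `attach_context_by_cooccurrence()` finds each pair's context as
the first abstract, in file order, in which both names occur
(case-insensitive substring match) and drops pairs that never co-occur,
reporting the count. Multi-class corpora pass through
`to_multiclass_instances()` unchanged, with the label set frozen in sorted
order.

## Tokenization and encoding

`wordpiece_tokenize()` is greedy longest-match-first sub-word
segmentation: repeatedly take the longest vocabulary piece prefixing the
remaining characters, continuation pieces carrying `##`; any dead end maps
the whole word to `[UNK]`. Basic tokenization lowercases (the uncased
convention), isolates punctuation, and splits CJK ideographs one character
per token so Chinese text is supported transparently. Words over 100
characters are `[UNK]` by fiat.

`encode_pair()` lays a pair out as `[CLS] A [SEP] B [SEP] [PAD]…` with
segment 0 through the first `[SEP]`, segment 1 after it, positions
0…max_len−1, and an attention mask that is 0 exactly on padding. When a
pair exceeds `max_len` the currently longer side loses tokens from its end
until the pair fits — the corpus formats do not prescribe a truncation
rule, and longest-first removal spares the short entity-pair sentence.
Note the practical consequence explored below: the context document must
actually fit, or the evidence for the label is silently cut off.

`build_vocab()` induces a miniature vocabulary: five specials, every
character seen (as both initial and `##` continuation, guaranteeing zero
`[UNK]` on the corpus itself), then whole words by descending frequency,
ties lexicographic.

## The encoder

Input embedding is the exact elementwise sum of token, segment and
position rows — an identity the tests assert with zero tolerance. The
stack applies L layers of masked multi-head scaled dot-product
self-attention (√d scaling; padding excluded as attention keys) and a
position-wise feed-forward network, both with residual connections and
post-sublayer layer normalization. Internals the architecture name does
not fix, resolved to the standard recipe: GELU feed-forward activation,
learned position embeddings, dropout on embeddings, attention weights and
sublayer outputs, truncated-normal initialization at scale 0.02, a tanh
pooler over the final `[CLS]` state. One deliberate deviation: there is no
layer normalization directly on the embedding sum, so a depth-zero encoder
returns the raw embedding — this keeps the embedding identity exact and
costs nothing at L ≥ 1 where the first sublayer normalizes anyway.

`count_parameters()` gives the closed-form total of embeddings, per-layer
weights and pooler; instantiated checkpoints match it element for element,
and the 12-layer/768-hidden/12-head geometry lands within 1% of the
published 110M figure.

## Pre-training

Two objectives. *Masked tokens*: 15% of real (non-special) positions are
selected, minimum one; of those 80% become `[MASK]`, 10% a random
vocabulary token, 10% stay (the standard fractions — the original
description says only that several tokens are erased). A transform block
(dense + GELU + layer normalization) feeds a decoder tied to the token
embedding table. *Next sentence*: consecutive sentence pairs within a
document are labeled `IsNext`; half the pairs, to within one, have the
second sentence replaced from a different document and are labeled
`NotNext`; a two-way classifier reads the pooled `[CLS]` vector.

Two schedule choices matter at miniature scale and are worth stating
plainly:

* **Each objective gets its own forward pass.** The masked-token objective
  sees the corrupted sequence; the next-sentence objective scores the
  intact pair. Corrupting 15% of tokens destroys much of the
  cross-segment evidence a topical-coherence decision rests on when
  sequences are only ~20 tokens long.
* **Alternating per-objective optimizer updates.** The masked-token
  gradient is roughly an order of magnitude larger than the next-sentence
  gradient, and with a single Adam state its noise dominates the second
  moments of the shared parameters, silencing the smaller signal. Each
  objective therefore keeps its own Adam moments and applies its own
  update per batch. With a shared state the next-sentence probe stays at
  chance for tens of epochs; with alternating updates it leaves chance
  under the same budget.

Gradients are clipped at global norm 1.0. Divergence (non-finite loss)
aborts with the epoch indicated. Everything is deterministic given the
seed; evaluation mode (no dropout) is bit-reproducible, and checkpoints
(JSON manifest + named tensors, shapes verified on load) round-trip to
bit-identical encodings.

## Fine-tuning with the CNN head

The classification head is the Kim-style multi-filter 1d-CNN: filters of
widths 3/4/5, 100 feature maps each, slide along the token axis over
full-hidden-size slices of the final encoder states ("valid" convolution —
windows never extend past the last real token), ReLU, then max-over-time
pooling; the 300 pooled features pass through dropout 0.5 and a dense
softmax. `[CLS]`/`[SEP]` rows participate in convolution; padding rows are
excluded from pooling; if fewer real tokens remain than a filter's width,
that filter contributes its bias through ReLU. The plain linear head
(dropout + dense softmax on the pooled `[CLS]` state) is also provided as
the baseline sequence classifier.

Binary tasks train under the margin ranking loss
`Σ max{0, 1 − g(d) + g(d′)}` where `g` is the softmax probability of the
positive class, `d` ranges over positive and `d′` over negative training
documents. Pairing is by shuffled index within each mini-batch, cycling
the shorter side (an all-pairs option exists); a batch containing a single
class falls back to cross-entropy for that step, since the margin is
undefined without both sides. Multi-class tasks use softmax cross-entropy.

Fine-tuning restores the pre-trained encoder and back-propagates head
error through every layer into the embedding tables (verified by
finite-difference agreement at 1e-4 and by checkpoint diffs); with
`freeze_encoder = TRUE` the encoder is bit-identical afterwards and only
the head trains. The freshly initialized head may take a larger learning
rate than the pre-trained encoder (`head_lr`, default equal to `lr`) — a
standard practice that matters here because max-over-time pooling routes
gradient only through each map's argmax window, making head training
signal sparse.

Optimization is Adam at a fixed rate — 5e-5 is the package-wide default,
matching the printed setting of the full-scale experiments; the miniature
benchmark (below) uses 3e-4/3e-3 because a 2-layer encoder trained from a
600-piece vocabulary is far from the regime that 5e-5 was tuned for. The
decay-0.95 AdaDelta setting named alongside the static-embedding baseline
belongs to that baseline only; the baseline itself is supported
structurally as a frozen, randomly initialized depth-zero encoder
(external embedding files are deliberately not required).

## Evaluation

`confusion()` produces one-vs-rest TP/FP/FN per class;
`prf()` applies P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), with 0/0
defined as 0. Multi-class summaries are micro averages (counts pooled
before the formulas); the official temporal-challenge scorer's
partial-credit closure rules are out of scope, and published
temporal-challenge rows are not directly comparable to the micro average
for that reason. `cross_validate()` runs stratified k-fold (sizes within
one; a class smaller than k relaxes stratification with a warning; every
sample tested exactly once).

## The synthetic generator: what it emulates and what it does not

`generate_relation_corpus()` produces PubTator-writable documents with
exact character offsets: each document mentions a few typed entities, and
related chemical-disease pairs co-occur in a sentence where a trigger verb
("induced", "caused", "provoked") links the two names. Whether a pair is
related is a **corpus-level fact table** drawn once per seed
(`synth_facts()`), mirroring the fact-consistency of real corpora — the
same pair means the same thing in every document that reports it. At the
default easy regime the table factorizes: a pair is related iff the
chemical belongs to an "inducing" subset and the disease to an
"inducible" subset, each drawn at probability √0.3 so the overall density
is 0.3. Unrelated pairs never share a sentence, so a trigger-pattern
matcher (`trigger_oracle()`) recovers the gold labels with F1 = 1.0 — the
separability guarantee behind every learnability test. Difficulty knobs —
`trigger_dropout`, `distractor_triggers`, `factored_facts = FALSE`
(independent per-pair facts that must be memorized) — harden the regime;
defaults are easy on purpose, so that a tiny encoder can learn the signal
quickly.

`generate_pretrain_corpus()` writes multi-document text with (i)
Zipf-distributed shared head words, (ii) a document-specific topical
vocabulary (the rarer words are partitioned into buckets, each document
writing mostly in its own bucket), (iii) discourse-style continuity (each
sentence opens with the previous sentence's last content word), and (iv)
entity-trigger sentences that report only true facts from the same fact
table. Points (ii)–(iii) are what make the next-sentence objective
learnable; point (iv) is what makes pre-training *useful* downstream — as
with real literature, the unlabeled text carries the facts the labeled
task asks about.

What the generator does **not** emulate: real biomedical syntax and
morphology, multi-word and nested entity mentions, anaphora, relation
evidence spread across sentences, annotation noise, and class imbalance
beyond what pool exhaustion produces. Passing the learnability tests
therefore shows the pipeline is correctly wired and can extract a planted
lexical signal — it does not predict F1 on BC5CDR-scale data, which
additionally needs full-scale pre-training.

The printed worked-example record (PMID 1601297) ships as
`fixture_1601297()`. One textual note: the printed abstract and its own
printed offsets disagree by one character at the last mention; the fixture
uses the text variant ("ischemia, and bundle branch block") consistent
with all nine offsets, which verify exactly. Mention surfaces are compared
case-folded because the printed annotation table capitalizes surfaces
independently of the running text; offsets are enforced exactly.

## The miniature benchmark

`miniature_conditions()` fixes the package's end-to-end study conditions:

| stage | setting |
|---|---|
| corpus | 150 documents, 2 chemicals × 4 diseases each, fact density 0.3, factored facts |
| pre-training text | 60 documents × 10 sentences, fact-aware |
| vocabulary | 600 pieces |
| encoder | L = 2, H = 64, A = 2, F = 256, P = 96, dropout 0.1 |
| pre-training | 25 epochs, batch 16, Adam 1e-3, 32-token pairs |
| fine-tuning | 500 instances (350 train / 150 held out), 80-token pairs, batch 16, 5 epochs, CNN head 3/4/5 × 100, dropout 0.5, ranking loss, encoder 3e-4 / head 3e-3 |

The 80-token fine-tuning length is not cosmetic: synthetic abstracts run
to ~85 tokens, and truncating below that cuts off the trigger sentence for
a fraction of instances, capping attainable F1 — the single most
instructive failure mode met while building the package. The problem sizes
were chosen as the smallest at which every stage's behavior is
demonstrable; the whole benchmark (pre-training included) runs in a few
minutes on one CPU.

Under these conditions the acceptance suite verifies: the combined
pre-training loss decreases and held-out masked-token perplexity beats the
uniform baseline; the next-sentence probe beats chance; fine-tuning
reaches held-out F1 ≥ 0.9; and across three fine-tuning seeds the mean
held-out F1 orders as pre-trained-unfrozen ≥ pre-trained-frozen and
≥ random-initialization — at the easy defaults all three variants
saturate near 1.0, so the inequalities hold as ties; the ordering is
strict in harder regimes that are out of the default test budget.

## Numerical notes

* Layer normalization uses ε = 1e-6; attention masking adds −1e9 before
  the softmax, which underflows to exact zero weight on padding.
* Backpropagation is hand-derived per component and verified against
  central finite differences (tolerance 1e-4 in tests; agreement in
  development was ~1e-10).
* All randomness flows through a single integer seed; stages derive
  sub-seeds by hashing the stage name (`derive_seed()`), so any stage
  reproduces in isolation. Library calls never disturb the caller's RNG
  state.
* Ties in max-over-time pooling resolve to the earliest window; ReLU
  gradients at exactly zero are treated as zero.
* Scores entering the ranking loss are validated to lie in [0, 1]; a
  non-finite training loss aborts with diagnostics rather than continuing.

## Known limitations

* No warmup or decay schedules, no mixed precision, single-device only.
* The ranking loss saturates pathologically at learning rates well above
  the benchmark setting (scores pinned to one class); cross-entropy is the
  robust fallback and the default for multi-class tasks.
* The temporal-relation XML dialect is not parsed; users convert to the
  canonical instance TSV externally.
* Entity recognition is out of scope: gold mentions are assumed, as in
  the chemical-disease task's relation-only setting.
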