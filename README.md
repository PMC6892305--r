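# medrex

Medical relation extraction with a from-scratch pre-trained transformer
encoder and a multi-filter 1d-CNN classification head, in plain R.

## What this package is for

Extracting relations between normalized biomedical entities — a chemical
and the disease it induces in a PubTator-annotated abstract, an herb and a
disease in a traditional-Chinese-medicine literature table, an event and a
time expression in a clinical note — is a classification problem, and the
annotated corpora for it are small: hundreds to a few thousand labeled
pairs per category, well below what a deep classifier trained from scratch
needs. `medrex` implements the pre-train-then-fine-tune remedy end to end
at desk scale, for researchers who want a fully inspectable, dependency-light
R implementation of every moving part:

* **Corpus IO** — PubTator format (title/abstract lines, tab-delimited
  mention and relation lines), tab-delimited relation tables with a
  separate literature file, and a canonical 7-column instance TSV.
* **Sample generation** — each instance is a sentence pair: sentence A is
  the two entity names, sentence B the title + abstract they co-occur in.
  Annotated pairs are positives; unannotated typed pairs are sampled
  uniformly per document as negatives at a 1:1 ratio, so the model trains
  balanced.
* **WordPiece tokenization** — greedy longest-match-first sub-word
  segmentation ("suxamethonium" → `su ##xa ##met ##hon ##ium`), sentence
  pairs encoded as `[CLS] A [SEP] B [SEP]` with segment and position
  indices.
* **Encoder** — input embedding as the exact sum of token, segment and
  position rows, then L layers of masked multi-head self-attention and
  position-wise feed-forward networks; pre-trained with the masked-token
  and next-sentence objectives. Geometry is configurable from miniature to
  the 12-layer/768-hidden/12-head base model (whose parameter count the
  package reproduces: 109,480,704 ≈ 110M).
* **CNN head and ranking loss** — filters of widths 3/4/5 with 100 feature
  maps each slide over the final token states, max-over-time pooled,
  dropout 0.5, softmax; binary tasks minimize the margin ranking loss
  `Σ max{0, 1 − g(d) + g(d′)}` over positive/negative document pairs, and
  the head's training error back-propagates into the encoder
  (hand-derived gradients, finite-difference verified).
* **Evaluation** — per-class and micro-averaged precision/recall/F1, and
  stratified k-fold cross-validation.
* **Synthetic data** — a generator producing PubTator corpora with exact
  offsets, a corpus-level chemical-disease fact table, and a lexical
  trigger signal ("X induced Y") that makes the labels exactly recoverable
  by a rule oracle — the ground the test suite stands on.

## A worked example

The printed chemical-disease example record ships with the package:

```r
library(medrex)

doc <- fixture_1601297()
doc
#> <document_record 1601297>
#>   title:    Electrocardiographic evidence of myocardial injury in psychiatrically
#>   abstract: 291 chars
#>   mentions: 9   relations: 2
```

Nine mentions normalize to one chemical concept and five disease concepts,
two of which are annotated as chemical-induced-disease relations. Sample
generation turns the two relations into positives and draws two negatives
from the three unannotated chemical-disease pairs:

```r
make_positive_samples(doc)[, c("instance_id", "sentence_a", "label")]
#>   instance_id                    sentence_a label
#> 1  1601297_p1 cocaine myocardial infarction     1
#> 2  1601297_p2   cocaine bundle branch block     1

make_negative_samples(doc, 2, generation_config(seed = 1))[, c("instance_id", "sentence_a", "label")]
#>   instance_id                sentence_a label
#> 1  1601297_n1     cocaine schizophrenic     0
#> 2  1601297_n2 cocaine myocardial injury     0
```

Each `sentence_a` is paired with the document text as `sentence_b`; the
pair is what the encoder consumes. The miniature pipeline end to end:

```r
cond <- miniature_conditions()          # the fixed desk-scale conditions
data <- miniature_data(cond)            # synthetic corpus, 500 instances, vocab
pt   <- miniature_pretrain(data, cond)  # 25 epochs of masked-token + next-sentence
model <- finetune(pt, data$train, data$dev,
                  miniature_finetune_config(cond, seed = 1))
predict(model, data$dev)[1:3, 1:2]      # labels + class scores
```

On the default conditions the held-out positive-class F1 reaches ≥ 0.9
within five epochs, the pre-training loss decreases, and the held-out
next-sentence probe beats chance — the quantities the acceptance script
recomputes (below). `summary(model)` prints the per-epoch training loss
and held-out metrics.

The pipeline is also scriptable stage by stage (synth → prepare →
pretrain → finetune → evaluate → predict) through `run()` or the thin CLI
wrapper in `inst/cli/medrex.R`; every stage writes a manifest with its
configuration, seed and input digests.

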