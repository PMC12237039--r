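---
title: "Joint relational triple extraction with adversarial embedding training"
author: "relexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint relational triple extraction with adversarial embedding training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relexr)
```

## The problem

Botanical descriptions — "Iris dichotoma is a perennial herb found on sunny
slopes…" — pack several facts about one plant into a sentence. Turning such
text into a knowledge graph requires extracting *relational triples*
(subject, relation, object): the plant name as head entity, an attribute
category (habit, habitat, flowering period, …) as the relation, and the
attribute mention as tail entity. The difficulty is *overlap*: most
sentences share one head entity across several triples (single entity
overlap, SEO), some repeat a whole entity pair under two relations (entity
pair overlap, EPO), and occasionally a subject mention sits inside an
object mention (subject-object overlap, SOO). Pipeline systems that first
detect entities and then classify relation per entity pair handle these
poorly; `relexr` implements a joint, tagging-based extractor.

## The model

Three stages share one contextual encoder and are trained jointly.

**Encoder.** Tokens are embedded as the sum of word, segment and position
vectors, `E = E_C + E_S + E_P`, wrapped in `[CLS]`/`[SEP]`, and passed
through a small bidirectional transformer ("tiny mode": 2 layers, 2 heads,
dimension 32 by default). Special-token rows are dropped before the heads;
all single-sentence inputs use segment 1.

**Relation classification** (multi-label). Three sentence vectors are
average-pooled at different granularities: `e1avg` over tokens, `e2avg`
over word chunks (each word's token vectors averaged first), and `e3avg`
over fixed windows of 4 tokens (the final, possibly shorter window is
averaged over its true length — this keeps window pooling identical to
global pooling when the window exceeds the sentence). The fused vector
feeds a linear-sigmoid classifier:

\[ p_{rel} = \sigma\!\big(w_r(\alpha e1_{avg} + \beta e2_{avg} + \gamma e3_{avg}) + b_r\big). \]

Relations with \(p_{rel} > \lambda\) (strict, default \(\lambda = 0.5\))
are selected.

**Global correspondence matrix.** Every token pair (i, j) is scored as
\(p^{sub,obj}_{i,j} = \sigma(w_g[h_i^{sub};h_j^{obj}] + b_g)\): the
confidence that a subject mention starts at i and an object mention starts
at j. The subject and object views \(h^{sub}, h^{obj}\) are separate
linear projections of the encoder states (the formulation leaves open
whether the two views share parameters; separate views cost little and let
the two roles specialize). Padding positions are masked out.

**Relation-conditioned tagging.** For each selected relation j, every
token vector is concatenated with the relation embedding,
\(X_i = [h_i ; r_j]\), passed through scaled dot-product self-attention
\(H = \mathrm{softmax}(QK^\top/\sqrt{d_k})V\), and mapped to B/I/O
distributions for the subject and the object role separately. Spans are
decoded from the tag rows, subject × object span pairs are formed, and a
pair is kept only if the global matrix scores its two start positions at
least \(\lambda_g\) (default 0.5).

**Joint loss.** Three equally weighted terms: mean binary cross-entropy
over the relation slots; mean binary cross-entropy over the n² matrix
cells; and categorical cross-entropy of the tag rows normalized by
\(2 \cdot n \cdot n_r^{pot}\) (two roles, n tokens, \(n_r^{pot}\) selected
relations). Selected relations are the gold ones plus (by default 2)
sampled negative relations whose tag rows are all O, resampled each epoch,
so the taggers also learn to stay silent for wrong relations.

**Adversarial training (FGM).** Each optimization step runs two passes.
The clean pass backpropagates and retains gradients; the gradient g at the
shared word-embedding table defines the fast-gradient-method perturbation

\[ \Delta x = \varepsilon \, g / \lVert g \rVert_2 \]

(Frobenius norm over the whole table — all samples share one
perturbation). The table is perturbed, a second forward/backward pass adds
its gradients to the retained ones, the table is restored bit-for-bit, and
a single optimizer update applies the summed gradients. \(\varepsilon\)
defaults to 0.005 and is exposed (`train_control(epsilon = )`); the
feasible set is interpreted as the L2 ball of radius \(\varepsilon\), and
the perturbation is recomputed from scratch every batch. With
\(\varepsilon = 0\) the schedule degenerates to plain two-pass gradient
accumulation, which the test suite exploits as an exact contract.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.5 | relation decision threshold (strict >) |
| `lambda_g` | 0.5 | global-matrix filter threshold (>=) |
| `alpha, beta, gamma` | 1/3 each | fusion weights of the three pooled vectors; configurable, optionally trainable |
| `window` | 4 | token window of the third pooling level |
| `epsilon` | 0.005 | FGM scale at the word-embedding table |
| `lr` | 1e-4 | optimizer rate for fine-tuning-scale runs; from-scratch tiny encoders are trained at 3e-3 in this package's own experiments |
| `weight_decay` | 0.01 | decoupled (AdamW-style) regularization |
| `patience` | 30 | early-stopping epochs without dev-F1 improvement |
| `negative_relations` | 2 | all-O tag rows sampled per example |

The fusion weights default to equal thirds because the formulation calls
them scaling factors without giving values; they are exposed and can be
made trainable (`trainable_fusion = TRUE`). The relation-embedding
dimension defaults to the encoder dimension.

## Numerical and design choices

- **Optimizer.** Adaptive moments (Adam) with decoupled weight decay; the
  method description does not name an optimizer. Weight decay matters here
  because the tiny encoder is trained from scratch on small corpora and
  will otherwise memorize sentence layouts instead of token evidence.
- **Dropout (0.1) and cosine learning-rate decay** regularize and
  stabilize from-scratch training; both are exposed in `train_control()`.
  A whole-word-masking input-augmentation option (`mask_rate`) exists but
  defaults to off: masking a short object mention deletes the only
  evidence for its relation, which at small corpus sizes adds more label
  noise than regularization.
- **Layer normalization** follows each encoder sublayer (post-LN); it
  keeps token states at unit scale, which the linear heads need for usable
  gradient magnitudes at this width.
- **Tagger attention initialization.** `W_Q` and `W_K` start as the same
  matrix, so \(Q_i \cdot K_i = \lVert W^\top X_i\rVert^2 > 0\) and
  attention opens near-diagonal: each token initially reads mostly its own
  state. Sequence tagging needs per-token identity preserved; starting
  from uniform attention, which averages all tokens together, stalls the
  tagging loss for tens of epochs. Both matrices train independently
  afterwards.
- **BIO decoding** treats an orphan `I` (no preceding `B`/`I`) as `O`
  rather than promoting it to `B`: conservative decoding never emits a
  span whose start the tagger did not commit to.
- **One overlap label per sentence** with precedence
  EPO > SOO > SEO > normal (rarest and most specific wins), so pattern
  compositions sum to 100%.
- **Thresholds.** Relation selection is strict (`>`); the matrix filter is
  inclusive (`>=`). Raising either threshold can only shrink the output —
  a monotonicity the tests assert.
- **Duplicate triples** in input corpora are dropped with a warning;
  predicted duplicates arising from several relation taggers are merged on
  (subject span, relation, object span).
- **Numerics.** Training losses are computed from logits in fused,
  numerically stable form; the exported probability-space loss functions
  clip to [1e-7, 1 - 1e-7]. Tag distributions sum to 1 within 1e-6.
  Degenerate inputs (no selected relations, empty span lists, all-padding
  pools) return defined values (0 loss, empty lists) or explicit errors.
- **Spans** are token-indexed, 0-based, half-open; relation ids are
  1-based indices into the schema.

## The synthetic corpus

The "Landscape"-style plant corpus that motivated this architecture is not
publicly deposited, so the package ships a template generator
(`generate_corpus()`) that reproduces its statistical structure rather
than its surface text: 13 relation categories; 1-7 triples per sentence
(the 5+ bucket realized uniformly over 5-7); an overlap mix of SEO 83%,
normal 10%, SOO 5%, EPO 2%; plant-name subjects shared across a sentence's
triples; disjoint per-relation attribute vocabularies; filler tokens
between mentions so span boundaries are non-trivial. Entity mentions are
1-2 tokens, never sharing tokens within a sentence, so surface-string span
resolution is unambiguous and write/read round trips are exact. Vocabulary
sizes default to 24 plant names, 8 attributes per relation and 10 fillers
— small enough that a desk-scale model can learn every token, large
enough that held-out sentences contain unseen combinations.

What the generator does **not** emulate: real tokenizer noise, paraphrase,
Chinese character segmentation, mention ambiguity (the same string in two
roles), or any correlation between attributes of one plant. A model that
passes the held-out test here has learned token-level role and relation
evidence under overlap — not botany. Results on the synthetic corpus say
nothing about headline scores on the undeposited corpus; the package makes
no attempt to reproduce those numbers.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen so the full suite stays
within minutes on one CPU: formula oracles on ~100 random instances with
n ≤ 6 and dim ≤ 8; a pipeline-identity test on 100 generated sentences;
and a scaled-down learning run — 60 training / 20 held-out sentences,
dimension 32, 2 layers, 2 heads, batch 4, learning rate 3e-3, FGM at
\(\varepsilon = 0.005\), at most 200 epochs. Training monitors the
held-out F1 every epoch and keeps the best parameters.

## Known limitations

- No pretrained-checkpoint mode: the encoder is always trained from
  scratch. The whole-word-masking collator is provided for users who want
  to add domain-adaptive masked-LM pretraining, but no pretraining loop
  ships with the package.
- The matrix filter scores span *start* positions only, faithful to the
  global-matrix formulation; two spans sharing a start are not
  distinguished there (the taggers usually disambiguate).
- Micro-averaged exact matching only; no partial-credit span scoring, no
  confidence intervals.
- Single sentence, single segment; no cross-sentence coreference.
- **From-scratch training is supervision-limited at desk scale.** Under
  the default generator conditions, a 60-sentence training set gives each
  relation-specific attribute token only a handful of supervised
  occurrences, and the tagger's relation-token interaction flows only
  through attention (the concatenation \(X=[h;r]\) admits no bilinear
  readout). The scaled-down run overfits its training set to high
  exact-match F1 while held-out exact-match F1 plateaus far lower (the
  acceptance script reports both). The architecture expects a pretrained
  encoder to supply token priors; without one, held-out performance at
  this corpus size should be read as a floor, not as what the method
  achieves at full scale.
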