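---
title: "Prototype-guided multimodal molecular property prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-guided multimodal molecular property prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molproto)
```

## The model

`molproto` predicts molecular properties from two coupled views of a
molecule: its heavy-atom graph and a tokenized textual description. The
architecture has four stages.

**Graph branch.** Atom features (one-hot element over a fixed 100-symbol
vocabulary, one-hot degree 0–6, one-hot formal charge −2..+2, aromatic
flag; 113 dimensions) pass through a learnable linear input map into a
`d_g`-dimensional state. L rounds of GIN message passing follow:
each atom combines `(1 + eps)` times its own state with the sum of its
neighbors' states and applies a linear–ReLU–linear MLP; `eps` is learnable
per layer, initialized at 0. After *every* layer a sum readout produces a
graph-level vector, giving the hierarchical set `Z_g = {z_g^(1..L)}`.
Isolated atoms receive a zero neighbor aggregate. Readout is
permutation-invariant, so the encoding depends only on the graph's
isomorphism class — the tests assert this over random relabelings.

**Text branch.** A pluggable provider maps each token to a
`d_t`-dimensional embedding. The bundled default is a deterministic
hash-based embedder: each token string hashes to a seed that draws a fixed
unit-norm Gaussian vector, so embeddings are reproducible, context-free,
and require no external weights. Token embeddings are mean-pooled into
`z_t^(0)` and refined by L pre-norm transformer layers, each treating the
pooled vector as a length-1 sequence. We follow the refinement equation
literally: its input and output are single vectors, so self-attention over
one token reduces to the value/output projections and multi-head
decomposition is mathematically collapsed into one full-rank product. A
sequence-level alternative (pool after refinement) would be a different
model; the equation as written types the transformer as vector-to-vector,
and we implement exactly that.

**Fusion.** At each layer, the graph vector is projected into text space
(`W_{g→t} z_g`, no bias — the projection equations show none) and used as
the key and value against the text query, and symmetrically for
text-to-graph; a residual adds the result to the original vector. With
pooled per-layer vectors the key set is a singleton, the softmax weight is
exactly 1, and fusion reduces to the literal fixed point
`ẑ_t = z_t + W_{g→t} z_g`. The scaling by `sqrt(d_g)` is applied in both
directions as printed, and is inert in singleton mode. `cross_attend()`
also accepts a matrix of keys for non-degenerate, token-level attention;
the default pipeline stays with the vector-typed equations.

**Prototype space and losses.** The fused per-layer vectors are
mean-pooled over layers, affinely projected into a `d_p`-dimensional
space shared by both modalities, and compared with C·N learnable
prototypes (N per class; C = 1 for regression, reflecting the continuous
output) by squared Euclidean distance. The log-ratio transform
`s = log((D + 1)/(D + ε))` maps distances to similarities in
`(0, log(1/ε)]`, strictly decreasing in D. The top-K scores are retained
(ties broken toward the lowest flat index, for determinism), softmaxed
over the *retained raw scores only* — gradients therefore flow only
through the selected K entries — and the two modalities' distributions
are pulled together by a KL divergence. Prediction uses only the fused
*graph* vectors: each layer owns a linear head and the final logits are
the mean of the L head outputs. The prototype contrastive loss is
InfoNCE-style over prototypes with cosine similarity and temperature τ;
the denominator keeps the anchor's self-similarity term, exactly as the
unrestricted double sum is written. For regression the pseudo-classes come
from a 2-means partition of the prototypes (Lloyd, 10 restarts, at most
100 iterations, fixed seed), recomputed once per epoch rather than per
step — the partition is a discrete, non-differentiable quantity, and
refreshing it per step would make the loss landscape noisier at no
benefit at this scale. Anchors in singleton clusters are skipped with a
warning.

The total objective is the weighted sum
`λ_align L_align + λ_pred L_pred + λ_proto L_proto`, optimized with Adam
(learning rate 8e-5, weight decay 1e-4, batch 128, cosine annealing over
100 epochs by default). All three weights default to 0.9, and N = K = 5,
the configuration reported as best in the sensitivity analysis of the
original study design.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 3 | shared depth of both branches; fusion pairs layers one-to-one, so the branches must agree on L |
| `d_g`, `d_t`, `d_p` | 64 | branch and prototype dimensionalities (dimensionless) |
| `N`, `K` | 5, 5 | prototypes per class; retained top-K entries (1 ≤ K ≤ C·N) |
| `epsilon` | 1e-6 | log-ratio constant; caps the similarity at log(1/ε) ≈ 13.8 |
| `eps_kl` | 1e-8 | probability floor for off-support entries in the KL |
| `tau` | 0.5 | contrastive temperature; smaller sharpens the prototype softmax |
| `lambda_*` | 0.9 | loss weights |
| `lr`, `weight_decay` | 8e-5, 1e-4 | Adam settings for full-scale runs |

The two modalities' top-K supports may differ, and a KL between
distributions living on different K-subsets is ill-defined. We therefore
embed both distributions in the full C·N-length space, floor off-support
entries at `eps_kl`, and renormalize; index correspondence between the
spaces is preserved and the divergence stays finite. An
intersection-of-supports variant is exposed in `alignment_loss()` for
comparison.

## Numerical choices

- **Prototype projection initialization.** `W_{g→p}` and `W_{t→p}` start
  at 0.02× Glorot scale with zero bias. The log-ratio constants (+1 in
  the numerator, ε in the denominator) make the similarity responsive
  only for distances of order 1; prototypes start at unit scale
  (i.i.d. normal, sd `1/sqrt(d_p)`), while the encoder outputs have
  norms in the tens. A near-zero projection places both modalities at
  O(1) distance from every prototype at the start of training, so the
  alignment loss has usable gradients from epoch 1; with plain Glorot
  init the initial distances are ~10³ and the prototype stage starts in
  the flat tail of the transform.
- **Desk-scale schedule.** `inst/configs/desk.yml` (L = 3, 64-dim
  branches, 20 epochs, batch 128) raises the learning rate to 1e-3 — the
  standard Adam rate for small networks — because the full-scale 8e-5
  rate is matched to a 100-epoch schedule. `inst/configs/paper.yml`
  keeps the full-scale values.
- **Determinism.** All randomness (initialization, shuffling, generator,
  k-means restarts, the hash embedder) derives from integer seeds;
  repeated runs are bit-identical, and checkpoints restore bit-identical
  predictions. Top-K ties and k-means cluster labels are ordered
  deterministically.
- **Degenerate inputs.** Empty graphs, empty token lists, single-class
  evaluation sets (ROC-AUC reported as missing, not 0), all-identical
  prototypes (degenerate-clustering error), and non-finite losses
  (training aborts with epoch/batch context) are handled explicitly.
- **Gradients.** Backpropagation is hand-derived (no autodiff dependency
  exists in this stack); the test suite checks every parameter of a full
  micro-model (2 molecules, L = 2, 8-dim branches, C = 2, N = 2, K = 2)
  against central finite differences at relative error < 1e-3, plus
  per-stage checks for the alignment path and the GIN readout.

## The synthetic generator

`generate_molecules()` emulates small-molecule benchmark fixtures: heavy-
atom counts are Gaussian around a configurable mean (default 13.3, the
average of the classic aqueous-solubility benchmark), molecules are
emitted as SMILES so the full parsing path is exercised, and each class
plants a distinct carbocycle (default: cyclopentane vs cyclohexane).
Decorations are random acyclic trees of C/N/O, so cycle search recovers
the planted motif exactly — class identity is structurally decidable,
which is what makes held-out recovery a meaningful test. Texts are class
templates naming the motif plus shuffled distractor tokens. Regression
targets are `y = α·(ring count) + N(0, σ)` with α = 1, σ = 0.1 and 1–3
planted rings joined by short linkers.

What the generator does *not* emulate: chemical realism of substituent
statistics, aromatic heterocycles, real label marginals of multi-task
toxicity panels, and any correlation structure between text and property
beyond the planted motif. Passing the end-to-end tests therefore shows
that the architecture can recover a planted structural/semantic signal
under label noise at desk scale — not that it reproduces benchmark
accuracy on real data, which requires pretrained text encoders and GPU
training outside this package's scope.

## Design decisions on open points

- **Shared L.** The fusion stage pairs layers one-to-one, so both
  branches use the same depth.
- **Multi-task data.** Datasets with several binary endpoints train with
  per-task binary cross-entropy over observed labels only and share a
  C = 2 prototype space; this is a documented surrogate, since the
  prototype construction is defined per discrete class.
- **Model selection.** When a split is supplied, the epoch with the best
  validation metric provides the returned parameters and is logged;
  without a split the final epoch is returned.
- **Bond features** are retained in the parsed graph but not used by the
  GIN aggregation, which combines node states only.
- **Regression stratification** uses 4 quantile bins of y, making the
  80/10/10 stratified split well-defined for continuous targets.

## Problem sizes used in the tests

Unit and property tests run on micro configurations (2–12 molecules,
8–16 dimensional branches). The end-to-end recovery tests use 400
generated records with the desk configuration and three training seeds
on a fixed split, asserting a majority outcome because 20-epoch training
runs on 40-record test sets are stochastic; the equation-level oracle
tests cover 50 random configurations each. These sizes were chosen so the
whole suite documents the method's behavior in about two minutes of CPU
time.

## Known limitations

- The default singleton-attention fusion is the literal reading of the
  vector-typed equations; it is linear given the projections, and the
  attention softmax is degenerate (weight 1). Token-level attention is
  available but not the tested default.
- The hash-based text provider carries no semantics: two synonymous
  tokens get unrelated embeddings. It stands in for a pretrained encoder
  only in the sense of satisfying the same contract deterministically.
- The prototype contrastive loss depends only on the prototypes, not on
  the data; it shapes the anchor geometry while the alignment loss is the
  only force coupling prototypes to embeddings.
- Training is plain R matrix algebra on CPU: ~7 s for 320 molecules ×
  20 epochs at the desk configuration, adequate for method study, not for
  41k-molecule screens.
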