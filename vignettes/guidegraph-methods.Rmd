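---
title: "guidegraph: methods, modeling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{guidegraph: methods, modeling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidegraph)
```

## The problem

On-target editing efficiency of a CRISPR guide RNA varies widely between
guides, and models that read the 20-nt spacer as a flat character string
discard the guide's fold. A guide that sequesters its seed region in a
stable hairpin behaves differently from an unstructured one with the same
composition. `guidegraph` makes the fold a first-class input: each guide
becomes a graph whose nodes are nucleotides and whose edges carry two
relations — backbone adjacency and base pairing — and a graph neural
network regresses editing efficiency (percent, 0–100) on that graph.

## Guide graphs

For a guide of length $n$ (20 for a bare Cas9 spacer; longer in extended
mode when scaffold sequence is included, e.g. 20 + 75 nt), the graph
$G = (V, E)$ has $|V| = n$ nodes in 5'→3' order (0-based positions).
Edges:

* **sequential**: $\{p, p+1\}$ for $p = 0, \dots, n-2$ (the
  phosphodiester backbone), and
* **structural**: $\{i, j\}$ for every base pair $(i, j)$ of the
  secondary structure.

Both are symmetric relations, and the attention/convolution operators
consume directed arcs, so each undirected edge is materialized as two
reciprocal arcs with a type tag. The type tag is *not* used by the
default model (edges are homogeneous in message passing); it exists so
the structural channel can be switched off cleanly
(`drop_structural_edges()`) for ablation experiments. Arc order is
deterministic (sequential block, then structural, each ascending by
src/dst), so graph construction is bit-stable.

Node features default to one-hot encoding (fixed column order A, C, G,
U; T→U normalization at ingest; ambiguity codes are rejected under the
strict policy or smeared to 0.25-rows under the uniform policy).
Per-nucleotide embedding matrices — the kind produced by pretrained RNA
language models — can be supplied instead through a plain-text block
format (`>id nrow ncol` headers), with row counts validated against
sequence lengths.

## Secondary structures

Structures are handled in dot-bracket notation. The parser uses stack
discipline, rejects pseudoknot bracket families outright (round brackets
only — 20-nt spacers do not need them), and round-trips exactly with the
serializer, which in turn refuses crossing pair sets.

When no structure is supplied, `predict_structure()` runs a
Nussinov-style dynamic program maximizing the number of allowed base
pairs. Defaults: allowed pairs $\{AU, UA, GC, CG, GU, UG\}$ (Watson–Crick
plus wobble) and minimum hairpin loop of 3 unpaired bases, the standard
stereochemical floor. This predictor is deliberately *not* a
thermodynamic or learned folder; it is a transparent, deterministic
stand-in adequate for exercising graph construction end-to-end. Real
analyses should feed externally predicted structures via dot-bracket
files; the package folds exactly the sequence it is given (spacer-only or
extended). Traceback ties are broken deterministically — prefer leaving
the 5' position unpaired, otherwise pair it with the smallest feasible
partner — so outputs are reproducible. The DP's optimality is checked in
the test suite against exhaustive enumeration of all non-crossing
pairings on short random sequences.

## The regression network

Three stages, matching the smallest faithful instance of a
NodeMLP / graph-attention / graph-convolution stack:

1. **NodeMLP** — 2 fully connected ReLU layers applied per node
   (width = `hidden_dim`, default 128).
2. **Graph attention** — 1 layer, 4 heads (concatenated). For arc
   $s \to t$ and head $k$ with projected features $z = W_k h$, the score
   is $e_{st} = \mathrm{LeakyReLU}(a_{src}^\top z_s + a_{dst}^\top z_t)$
   and $\alpha_{st} = \mathrm{softmax}_s(e_{st})$, so each node's
   incoming weights sum to 1. Self-loop arcs are always added, which
   both stabilizes the softmax and makes a single-node graph
   well-defined (its attention degenerates to the self-loop).
3. **Graph convolution** — sum aggregation over neighbors plus self,
   followed by a linear map and ReLU. Sum (rather than mean) aggregation
   is intentional: it makes node degree visible, which is how the
   network senses whether a nucleotide is base-paired at all.
4. **Readout and head** — global mean pooling (sum and max available)
   and a 2-layer regression head to a scalar percent.

**Positional channels.** A mean-pooled 2-hop GNN on a 20-node chain
cannot otherwise distinguish position 3 from position 12, yet
position-specific nucleotide effects are central to guide efficiency (the
seed and near-PAM regions). The model therefore appends `positional_dim`
(default 9) channels to the node features: relative position
$p/(n-1)$ plus sin/cos pairs at geometric frequencies. Positions are
stored on the graph (`positions` field), not inferred from row order, so
predictions are exactly equivariant under node relabeling. Setting
`positional_dim = 0` recovers a purely structural model.

**Training.** Adam (default learning rate $10^{-3}$, batch 64, max 100
epochs), minimizing MSE on the raw 0–100 percent scale, early stopping on
validation MSE with patience 10 and best-epoch parameter restoration.
Labels are not standardized; instead the regression head's output bias is
initialized to the training-label mean — without this, Adam's bounded
per-step updates spend tens of epochs merely climbing from 0 to the label
mean. Dropout (default 0.1) is active only during training; evaluation
mode is a pure function. Initialization, shuffling and dropout all draw
from one stream seeded by `config$seed`, so training histories and
predictions are bit-reproducible. The exact layer widths, head counts and
pooling of any particular published graph model of this family are not
recoverable from open descriptions; the defaults here are declared, not
inferred, and the small seeded `random_search()` (uniform sampling over
discrete candidate sets, argmin validation MSE) is the supported way to
tune them.

Fine-tuning (`fine_tune()`) continues optimization from trained
parameters at a reduced learning rate (default one tenth), the standard
transfer-learning recipe for porting a model to a related editing system
(prime or base editing) with a smaller labelled set.

Gradients are computed by hand-written analytic backpropagation through
the attention softmax, aggregations and poolings (there is no deep
learning framework in a plain R stack); during development the analytic
gradients were verified against central finite differences to relative
error ~1e-7, and the batched forward pass is vectorized over a
block-diagonal batch graph so training n = 2000 guides takes minutes on
one CPU.

## Evaluation machinery

* **Metrics** — Spearman (average ranks on ties), Pearson, MSE, with
  explicit errors on undefined cases (constant vectors) instead of NaN
  propagation.
* **Splits** — seeded balanced $k$-fold plans and fraction holdouts;
  plans are values, not side effects, so they can be written down and
  replayed.
* **Redundancy filtering** — test guides too similar to any training
  guide leak performance. `similarity()` is optimal global alignment
  identity with unit match and zero mismatch/gap scores (equivalently,
  LCS length) divided by the longer length; `filter_by_similarity()`
  drops test records at or above the threshold (default 0.9) and reports
  per-record maxima and the redundancy rate. One transparent definition
  replaces heavier external alignment tools; the filter is idempotent.
* **Permutation test** — observed statistic = Spearman(preds, labels);
  null from B seeded label shuffles (default 999); two-sided p with the
  add-one correction $p = (1 + \#\{|r_b| \ge |r|\})/(B+1)$, so the
  smallest attainable p is $1/(B+1)$ and p-values are calibrated
  (super-uniform) under the null — a property the acceptance suite
  checks empirically.

## Interpretability

`extract_attention()` exposes the final attention layer's arc weights
(heads averaged by default; per-head available). `position_importance()`
aggregates them into per-position scores across a set of same-length
graphs: *incoming* (mean total weight on arcs into the position),
*outgoing* (mean total on arcs out of it) and *combined* — the product of
the normalized incoming and outgoing scores, renormalized — which
highlights hub positions high in both. One caveat worth stating plainly:
under the softmax contract every node's incoming mass is exactly 1, so
for model-derived attention the incoming profile is flat (up to
degenerate nodes) and the discriminative signal lives in the
outgoing/combined scores; the aggregation accepts arbitrary nonnegative
arc weights, for which all three channels are informative. Head and
layer aggregation are choices (mean over heads, final layer) made here
because no canonical convention exists.

## The synthetic world

`synthetic_spec()` / `generate_dataset()` plant a *known* efficiency
function so that learning, ablation and interpretability claims are
testable without external data:

$$\mathrm{eff} = \mathrm{base} + w_{struct} \cdot \frac{\#\text{paired bases}}{n} + \sum_p W[p, \mathrm{nt}(p)] + \varepsilon,\quad \varepsilon \sim N(0, \sigma^2),$$

clipped to $[0, 100]$. Defaults: base 50, $w_{struct} = 30$ (percent from
fully unpaired to fully paired), position weights drawn once per spec
from $N(0, 5^2)$ on the functionally important spacer positions
(5' seed 2–6 and 3' near-PAM 15–19, 0-based) and zero elsewhere, noise
$\sigma = 5$. Sequences are uniform over A/C/G/U except that half the
records (default `hairpin_fraction = 0.5`) carry a planted complementary
stem (arms of length 4 at the sequence ends), guaranteeing structural
variation; structures come from the package's own predictor. The two
channels were chosen to mirror the two information sources the model
integrates — structure via paired fraction, sequence via
position-specific effects — so ablation *directions* (removing structural
edges hurts on structure-dominant data; replacing informative features
with one-hot hurts on sequence-dominant data) are reproducible
properties. Ablation *magnitudes* reported on real benchmark data are
not targeted: they depend on real datasets and pretrained externals.

`planted_embedding_features()` provides the synthetic stand-in for
language-model embeddings: the per-position planted effect as an explicit
feature column plus the one-hot channels.

What a green test on this world does **not** establish: performance on
real editing data. The generator has no PAM context, no chromatin, no
indel-spectrum biology, additive effects only, and its structures come
from pair maximization rather than thermodynamics. It establishes that
the machinery — graph construction, optimization, evaluation,
significance testing, attention aggregation — does what it claims when
the truth is known.

## Numerical choices and degenerate inputs

* Efficiency is percent (0–100) end-to-end; MSE values are therefore in
  squared percent.
* Attention softmax subtracts the per-destination maximum before
  exponentiation (overflow-safe).
* Single-node graphs: no arcs; self-loops keep attention, convolution
  and pooling defined.
* Adjacent base pairs (impossible under `min_loop` ≥ 1) would duplicate
  a backbone edge and are dropped by `build_edges()`.
* Ties in rank-based code break deterministically (ascending position in
  importance rankings; average ranks in Spearman).
* Checkpoints are opaque serialized objects with a JSON sidecar (config,
  feature dimension, seed, parameter count and checksum); loading
  verifies the checksum and errors on corruption rather than predicting
  garbage.
* `holdout_split` rounds the test size (`round(fraction * n)`) and keeps
  at least one record on each side.

## Known limitations

* The structure predictor maximizes pair count; it will happily produce
  maximally paired structures for composition-balanced sequences where a
  thermodynamic folder would not. Feed real predictions in via
  dot-bracket files for serious use.
* One similarity definition (LCS identity) stands in for the various
  alignment-tool scorings used in the field; absolute redundancy rates
  are comparable only within this definition.
* The network is small and CPU-bound by design; hundreds of thousands of
  guides or very deep stacks are out of scope.
* Extended (spacer + scaffold) mode treats the full sequence as one
  backbone chain; no special spacer/scaffold junction edge is added.
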