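---
title: "Graph feature auto-encoders: models, masking protocols, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph feature auto-encoders: models, masking protocols, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfae)
```

## The problem

Molecular interaction networks — transcription-factor/gene regulatory
networks, protein–protein interaction maps, genetic interaction screens —
summarise biological processes as graphs, while omics experiments measure
the activity of the same genes as real-valued profiles across conditions or
cells. The two views are complementary: interacting genes tend to have
related expression, and expression similarity is informative about
interactions. `gfae` treats this coupling as a prediction problem in both
directions:

1. **Structure from features** — embed the network with a graph
   auto-encoder and measure how well held-out edges are recovered and how
   much expression variance the embedding explains.
2. **Features from structure** — train message-passing networks end to end
   to predict unobserved expression values, using the network as the
   propagation substrate. This covers the practical task of imputing
   missing values, e.g. dropouts in single-cell RNA-seq.

Throughout, the graph $\mathcal{G} = (\mathcal{V}, \mathcal{E})$ is
undirected and unweighted with $N$ nodes, adjacency $\mathbf{A}$, and node
features $\mathbf{X} \in \mathbb{R}^{N \times Q}$ (genes by experiments).

## The structural graph auto-encoder

The encoder is a two-layer graph convolutional network using the
symmetrically normalised adjacency with self-loops,
$\tilde{\mathbf{A}} = \mathbf{D}^{-1/2}(\mathbf{A} + \mathbf{I})\mathbf{D}^{-1/2}$
(degrees recomputed from $\mathbf{A} + \mathbf{I}$, so isolated nodes are
well defined and the operator's spectrum lies in $[-1, 1]$):

$$\mathbf{Z} = \tilde{\mathbf{A}}\,\mathrm{ReLU}(\tilde{\mathbf{A}} \mathbf{X} \mathbf{W}_0)\,\mathbf{W}_1,$$

with identity output activation. The decoder scores a node pair by the
logistic inner product $\hat{A}_{ij} = \sigma(z_i^\top z_j)$. Because real
networks are sparse, the reconstruction loss is a full-matrix binary
cross-entropy with the positive class reweighted by
$(N^2 - 2|\mathcal{E}|) / (2|\mathcal{E}|)$ and the total normalised by
$N^2$; a cross-entropy restricted to present edges alone has a degenerate
minimum (score everything as an edge), so the negative terms are required
for a usable objective. Training is full-batch Adam. Optimiser choice,
dropout default (0) and the 85/5/10 train/validation/test edge split follow
the conventions of the non-probabilistic graph auto-encoder literature; the
variational variant is deliberately out of scope.

Embedding quality is measured three ways: AUC and average precision on
held-out edges against an equal number of uniformly sampled non-edges, and
*variance explained* — the $R^2$ of one joint ordinary-least-squares
readout $\mathbf{X} \approx [\mathbf{Z}, \mathbf{1}]\mathbf{B}$, with the
total sum of squares about column means. The $R^2$-with-intercept
definition is this package's own (reasonable definitions differ in whether
they centre or regularise); a rank-deficient design falls back to the
minimum-norm solution rather than failing.

Five input settings are compared: identity (one-hot) features on the real
graph, expression features on the real graph, both on an Erdős–Rényi graph
of matched density, and a no-training "expression" setting that scores a
candidate pair directly by the absolute Pearson correlation of the two
feature rows. One-hot inputs give each node a distinct but
functionally meaningless feature, so the embedding can only encode
topology — making the with/without-expression contrast interpretable.

## Message passing for end-to-end feature prediction

The feature-prediction networks stack two convolution layers (input → 64 →
32, ReLU after each) and a linear readout
$\tilde{x}_i = \mathbf{W} h_i + b$ with no output nonlinearity, trained
under mean squared error restricted to train-visible entries. Four
convolution layers are implemented:

* **message-passing GCN**:
  $h'_i = \sum_{j \in N(i) \cup i} \big(\deg i \cdot \deg j\big)^{-1/2} \mathbf{W} h_j$
  — algebraically identical to one dense $\tilde{\mathbf{A}} \mathbf{H}
  \mathbf{W}$ application (the test suite asserts this equivalence
  exactly). Degrees are counted with self-loops, consistent with
  $\tilde{\mathbf{A}}$; the convention without self-loops would change
  every coefficient but not the structure of the layer.
* **GraphSAGE**: $h'_i = \mathbf{W}_1 h_i + \mathbf{W}_2\,
  \mathrm{mean}_{j \in N(i) \cup i}\, h_j$. The closed-neighbourhood mean
  (self included) is implemented exactly as written here, which differs
  from the original GraphSAGE formulation (self excluded, concatenated).
* **GraphConv**: $h'_i = \mathbf{W}_1 h_i + \sum_{j \in N(i)} \mathbf{W}_2
  h_j$ — unnormalised sum aggregation, self excluded. On graphs with
  non-trivial mean degree the sum makes activations scale with degree,
  which shows up in practice as slow, unstable optimisation; this is a
  property of the layer, not an implementation artefact, and mirrors its
  high-variance behaviour in feature-prediction benchmarks.
* **FeatGraphConv**: $g_i = \mathbf{W}_1 h_i$, then
  $h'_i = \mathbf{W}_2 \big(g_i \,\|\, \mathrm{mean}_{j \in N(i) \cup i}\, g_j\big)$.
  Messages are transformed before pooling, and the update sees the node's
  own transformed state *concatenated* with the neighbourhood aggregate, so
  it can learn how much to trust self versus neighbourhood when
  reconstructing features. With $\mathbf{W}_1 = \mathbf{I}$ and
  $\mathbf{W}_2 = [\mathbf{I} \,|\, \mathbf{0}]$ the layer is exactly the
  identity map — the property that makes it well suited to feature
  reconstruction, and one the test suite checks literally.

All four layers are permutation equivariant and are verified against
per-node loop oracles on random graphs. Gradients for every layer are
hand-derived (the package implements its own reverse-mode pass over sparse
propagation operators) and checked against central finite differences.

Training is transductive: message passing runs over the full graph every
step, and only target values are hidden. The inter-layer ReLU and the
absence of dropout in this stack are this package's choices where the
framework leaves them open. The reference epoch budget is 20,000 with
learning rate 0.001; a 500-epoch fast profile (`gfae_config(fast = TRUE)`,
the default) is used for routine runs, tests and the acceptance script.

## Masking protocols

**Experiment split.** Both experiments (columns) and genes (rows) are
split. For each target experiment, a model sees the non-target columns of
*all* genes plus the whole graph, and is trained on the target-column
values of the training genes only; it is scored on the held-out genes. One
model is trained per target column, which keeps regression baselines
(one output per gene) comparable. The contract that no held-out target
value ever reaches the loss is enforced by construction and tested by
poisoning held-out targets with `NaN` and asserting finite training.
Because holding out every column in turn is quadratic in cost, the driver
samples 10% of columns per seed as targets by default.

**Imputation (entrywise) masking.** Matrix entries are split at random into
$K$ folds; per fold the test mask is the exact logical complement of the
train mask within the eligible entries. For sparse single-cell matrices,
`nonzero_only = TRUE` keeps zero entries permanently train-visible so that
only genuinely measured values are ever scored. The default driver
evaluates one fold per seed at $K = 10$ — each evaluation holds out 10% of
entries — and aggregates across seeds; running all $K$ folds for every
method multiplies cost tenfold without changing the estimand.

The imputation driver's default input convention deserves emphasis: the
complete matrix is the model input at training and evaluation, and the
masks govern only which entries the loss (train) and the metric (test)
read. This measures *reconstruction ability in an auto-encoder framework*:
a model trained to reproduce one random subset of entries is scored on the
complementary subset. A strict missing-value variant
(`input = "train_masked"`, test entries zeroed in the input throughout) is
also provided; note that with $Q$ smaller than the 32-unit bottleneck this
variant rewards memorising observed entries and generalises poorly, which
is visible as test error growing with training time.

## Baselines

Linear regression (exact least squares, multi-output), a 100-tree random
forest (per target column), and a multilayer perceptron with the same
64/32 widths and trainer as the graph models but no message passing — so
the graph's contribution is isolated as the only difference. The MLP also
serves as the auto-encoder baseline under imputation masking with the same
masking contract. MAGIC, an external published imputation tool, is not
reimplemented or wrapped; its role as an external comparator is out of
scope here.

## The synthetic generator

`erdos_renyi_graph(n, p)` draws $G(n, p)$ graphs;
`two_block_graph(n, p_in, p_out)` plants two equal communities;
`smooth_features(g, q, steps, noise_sd)` draws an i.i.d. standard-normal
base signal, applies $\tilde{\mathbf{A}}$ `steps` times, and adds Gaussian
noise. The coupling mechanism is exactly the propagation operator the
models exploit, which makes "graph structure helps feature prediction"
true by construction and therefore testable.

One numerical subtlety: the smoothing operator's bulk spectrum contracts by
roughly $\bar{d}^{-1/2}$ per step, so at the default conditions (mean
degree ≈ 15, 4 steps) the raw diffused signal collapses to column-constant
within a fraction of a percent and any fixed noise level would drown it.
Each smoothed column is therefore rescaled to unit variance before noise is
added, making `noise_sd` interpretable as noise relative to the retained
graph-smooth signal; `rescale = FALSE` exposes the raw contraction, whose
monotonicity the test suite checks.

Default study conditions: $n = 300$, $p = 0.05$, $Q = 20$, 4 smoothing
steps, noise SD 0.3 — small enough for continuous testing, with coupling
strong enough that graph-aware methods measurably beat graph-free and
shuffled-graph controls. The structure-embedding comparison uses 200-node
two-block graphs with $p_{in} = 0.2$, $p_{out} = 0.02$. That choice comes
from a ceiling analysis: within-community non-edges are
information-theoretic ties for a topology-only embedding (edges inside a
block are exchangeable), so the achievable AUC against uniformly sampled
negatives is capped by the share of within-block negatives. Very dense
blocks push that ceiling above 0.85 (the regime used to demonstrate that
strong structure is learnable) but leave expression features nothing to
add; moderate densities leave headroom in which features — diffused on the
*full* graph, held-out edges included — carry edge-level information beyond
block membership, which is exactly the regime in which the
expression-plus-graph setting can beat graph-only input.

What the generator does **not** emulate: count noise and zero inflation of
real single-cell data, scale-free degree distributions, directed or signed
regulatory effects, and feature structure not mediated by the graph.
Passing the synthetic checks therefore demonstrates correctness of the
machinery and the direction of the graph's contribution under controlled
coupling, not performance on any particular real dataset.

## Numerical and reproducibility choices

* Weights: seeded Glorot-uniform initialisation; Adam with
  $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$, full batch.
* Every stochastic entry point takes an integer seed, restores the
  caller's RNG state, and is bit-reproducible; trainers raise an error
  naming the epoch if the loss turns non-finite.
* Negative-edge sampling is uniform over non-edges by rejection, disjoint
  between validation and test sets.
* AUC counts ties as one half (Wilcoxon form); average precision uses step
  interpolation. Both are tested against $O(n^2)$ brute-force oracles.
* Degenerate inputs are handled explicitly: isolated nodes get degree 1
  from the self-loop; constant feature rows score 0 in correlation-based
  edge scoring; rank-deficient regression designs use minimum-norm
  solutions; self-edges in input files are dropped with a warning and
  duplicate edges merged.
* Node order after graph/feature alignment is lexicographic in the gene
  ID, so repeated runs over the same files produce identical matrices.

## Evaluation scale

Tests and the acceptance script run the full pipeline at the default study
conditions with 500-epoch training profiles, 3–10 seeds per comparison and
one imputation fold per seed. These sizes are the package's own evaluation
design: they are the smallest at which the qualitative orderings of
interest are stable across seeds, and all reported quantities are computed
at run time at exactly these sizes.

## Known limitations

* Full-batch training with a dense $N \times N$ decoder pass bounds the
  practical graph size to a few thousand nodes; minibatching and neighbour
  sampling are out of scope.
* Edge attributes, directed and weighted graphs are not modelled, matching
  the unweighted-interaction setting the framework targets.
* The imputation protocol's reconstruction reading (full-input) should not
  be confused with strict missing-data imputation; both are available and
  documented, and the strict variant's overfitting behaviour at small $Q$
  is inherent to unbottlenecked auto-encoders rather than fixable by
  tuning.
* Hyper-parameters are fixed, not searched; comparisons are like-for-like
  under one shared configuration.
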