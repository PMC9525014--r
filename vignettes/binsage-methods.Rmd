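---
title: "Graph-aware contig binning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-aware contig binning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`binsage` bins metagenomic contigs by combining contig-intrinsic features
with the assembly graph. This vignette explains the models, the
parameters that matter, what the synthetic data generator does and does
not emulate, and the design choices made where the method left room for
them.

## The two-stage embedding model

**Stage 1 — contig-specific embeddings (VAE).** Each contig is described
by 136 canonical tetranucleotide frequencies (a 4-mer and its reverse
complement are counted as one class; windows containing `N` are skipped)
and by its mean read depth in each sample. Composition is z-scored per
dimension; depth vectors are divided by their per-contig sum when more
than one sample is available (the scale-free differential-abundance
shape), or log1p-transformed and min-max scaled for a single sample,
where only relative magnitude carries information. An encoder–decoder
pair with two hidden layers of 512 units maps the features to a
32-dimensional Gaussian posterior. The loss is

* 0.1 × mean-squared reconstruction error of the composition block,
* 0.9 × mean-squared reconstruction error of the abundance block,
* `kl_weight` × KL(N(mu, sigma) ‖ N(0, I)).

The 10/90 split makes multi-sample abundance the dominant reconstruction
target while still retaining composition. The embedding used downstream
is the posterior mean, not a sample, so clustering is deterministic.

**Stage 2 — graph embeddings (coverage-aware GraphSAGE).** The assembly
graph contributes links whose read coverage `rc` measures how many reads
support the junction. Sampling distributions per contig `u`:

* positive neighbor: `P(v | u) ∝ rc(u, v)`;
* neighbor negative: `P(v | u) ∝ 1 / rc(u, v)`;
* disconnected contigs have no positive and draw negatives uniformly
  from all other contigs; degree-1 contigs draw negatives uniformly from
  non-neighbors.

Three GraphSAGE layers (hidden 512, output 64, ReLU except the last
layer) aggregate sampled neighbors by their mean and concatenate with the
node's own state. The unsupervised loss per positive pair `(u, v)` with
`Q` negatives is

```
J(z_u) = -rc_norm(u,v) * log σ(z_u·z_v) - Q * mean_n log σ(-z_u·z_vn)
```

with `rc_norm = rc / max(rc)` over all edges, so the strongest link has
weight 1 and an untagged GFA (all coverages 1) reduces to the ordinary
unweighted objective. The `Q·mean` reading of the negative expectation
equals the sum over the `Q` drawn negatives.

**Clustering.** Both embedding blocks are L2-normalized per contig and
concatenated (dimension 32 + 64 = 96 at the defaults), which makes the
cosine similarity on the concatenation the average of the per-block
cosine similarities. Iterative medoid clustering then grows one bin at a
time: seed at a random unassigned contig, repeatedly move the medoid to
the unassigned contig whose threshold-ball covers the most unassigned
contigs, and emit the final ball as a bin. The radius is chosen per
dataset from the pairwise cosine-distance histogram: the deepest valley
between the first (intra-cluster) density peak and the strongest later
(inter-cluster) peak, falling back to 0.1 when the distances are
unimodal. Raising the radius can only merge bins, never split them.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `vae_config(latent_dim)` | 32 | contig-specific embedding size |
| `vae_config(kl_weight)` | 1/(4·latent_dim) | posterior regularization (see below) |
| `vae_config(epochs)` | 100 | VAE training epochs |
| `gnn_config(learning_rate)` | 5e-5 | Adam step size for the GNN |
| `gnn_config(epochs)` | 100 | GNN training epochs (early stop may end sooner) |
| `gnn_config(Q)` | 5 | negatives per positive edge |
| `gnn_config(neighbor_negative_frac)` | 0.1 | share of negatives drawn from low-coverage neighbors |
| `cluster_embeddings(threshold)` | automatic | cosine radius of a bin |
| `run_pipeline(min_contig_length)` | 0 | length filter; long-read edges rarely need one |

Two defaults deserve their reasoning spelled out.

*KL weight.* With ~138 input dimensions and mean-squared reconstruction,
a KL weight of `1/latent_dim` is strong enough to collapse the weak,
many-dimensional composition signal before the encoder learns it — the
composition reconstruction error stays pinned at the z-score baseline
and compositionally distinct genomes land on top of each other in the
latent space. A quarter of that (`1/(4·latent_dim)`), ramped in linearly
over the first 10% of epochs, leaves enough capacity for composition
while still keeping the posterior near-Gaussian.

*Neighbor-negative mixing.* Drawing negatives among neighbors
(inverse-coverage) implements the idea that low-coverage links are
probably spurious. But on a graph whose true links have near-uniform
coverage, every neighbor is an equally likely "negative", and with `Q`
negatives per positive a fraction `f` of them hitting neighbors gives
each true link about `Q·f/deg` pushes per single pull — at `f = 0.5`,
`Q = 5`, degree 2 that is 1.25 pushes against 1 pull, and the equilibrium
similarity of genuine genome links becomes *negative*: the graph term
actively fights the graph. The default `f = 0.1` keeps the expected push
rate at ~0.25 per pull, preserving the targeting of low-coverage links
without overwhelming the positive signal on clean graphs.

*Early stopping* follows the plateau rule — stop when the loss has not
improved by more than `early_stop_delta` for two consecutive epochs —
applied to a 5-epoch moving average, because per-epoch losses are
resampled stochastic estimates and jitter by far more than a meaningful
plateau threshold.

*Checkpoint selection.* When a marker table is given, the concatenated
embeddings are clustered at every `checkpoint_every` epochs and scored by
the number of bins with >90% marker completeness and <5% duplication
(ties broken by summed completeness); gold labels, when provided, replace
that score with bp-weighted F1. Without either, the last epoch is used.

## The synthetic community generator

`generate_community()` plants the ground truth that every test and the
acceptance checks rely on. Each genome is sampled from its own 3rd-order
Markov chain, interpolated between one shared base chain and an
independent random chain by `composition_divergence`; the genome is cut
at random breakpoints into contigs; consecutive contigs are linked with
coverage ~ Normal(intra mean, 10% sd), spurious cross-genome links are
added at a configurable rate with their own (lower) coverage scale, and
per-sample contig depths are the genome's abundance profile times
Normal(1, 5%) noise. Markers come from a shared universe with each
genome carrying each marker exactly once. The default community —
5 genomes of 200 kb split into 20 contigs each (~10 kb contigs, the
scale of long-read assembly edges), 2 samples, divergence 0.6 — was
chosen so that planted genomes are as distinguishable by tetranucleotide
composition as genuinely distinct species are; at 1–2 kb contigs the
4-mer sampling noise swamps any realistic genome signal, which is a
property of the statistics, not of the implementation. Profiles:
`easy` (defaults), `graph_only` (divergence 0 — composition carries no
information and only abundance plus the graph can separate genomes),
`composition_only` (no edges), `hard` (divergence 0.05, 30% spurious
links at half the true coverage).

What the generator does **not** emulate: assembler artifacts (chimeras,
repeat-collapsed segments), strain-level variation, uneven within-genome
coverage, path (`P`) lines, or read-level errors. Passing tests on these
communities therefore show that the method recovers planted structure
through the intended mechanisms — not that it matches any particular
real-data benchmark.

## Numerical choices and degenerate inputs

* Logs inside the edge loss are clamped at 1e-9, so the loss is always
  finite.
* Sequences shorter than k (or all-N) get a zero composition row and are
  flagged; constant feature dimensions z-score to 0.
* All-zero depth vectors become the uniform profile 1/S.
* A GFA without coverage tags gets every edge coverage 1.0; a link whose
  own record carries no tag takes the arithmetic mean of its endpoint
  segments' coverages (the symmetric default; the mapping of per-segment
  coverage onto a link weight is not canonically defined).
* Duplicate links over the same unordered pair collapse to one edge with
  the maximum coverage; self-loops are dropped; orientation is parsed
  but collapsed to undirected edges.
* Ties in the medoid density search resolve to the first candidate in
  index order; the seed-contig order is drawn once per run from the run
  seed, and a single pipeline seed derives all stage seeds, so bins are
  bit-for-bit reproducible.
* GraphSAGE training is full-graph per step: a fan-out-capped neighbor
  sample is redrawn each epoch and applied as a row-normalized
  mean-aggregation operator; node mini-batches only select which loss
  terms enter a step. This is the same estimator as per-node minibatch
  GraphSAGE in expectation and keeps the hand-written backpropagation in
  plain matrix algebra.

## Validation scale

The test-suite and acceptance runs train the VAE for 200 epochs and the
GNN for 40 on communities of 100 contigs — sizes at which every check
(genome recovery, graph-adds-signal, degradation on noisy graphs,
determinism) completes in a few minutes on one CPU while leaving the
conclusions unchanged from longer runs.

## Known limitations

* The GNN is inductive: contigs with indistinguishable features receive
  indistinguishable embeddings, so the graph cannot split genomes whose
  composition *and* abundance profiles coincide — it can only sharpen
  distinctions that exist in the features.
* The spec-level clustering radius is global; datasets with clusters of
  very different tightness may need a manual threshold.
* Medoid clustering is greedy and order-dependent by design; the planted
  small-instance oracle pins its behavior, but it is not a global
  optimizer.
* Single-sample abundance carries little signal after normalization;
  composition and the graph then do most of the work.
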