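---
title: "Relative molecule self-attention: model, featurization and protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative molecule self-attention: model, featurization and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rmat` implements a transformer encoder for small-molecule property
prediction in which the self-attention layer is *relation-aware*: instead of
adding positional encodings to the inputs, every pair of atoms $(i, j)$
carries a relation embedding $b_{ij}$ that enters both the attention logits
and the attention-weighted values. The unnormalized score of one head is

$$
e_{ij} \;=\; (x_i W^Q)(x_j W^K)^\top
\;+\; (x_i W^Q)\, b^K_{ij}
\;+\; (x_j W^K)\, b^K_{ij}
\;+\; u^\top (x_j W^K)
\;+\; v^\top b^K_{ij},
$$

i.e. the vanilla query–key product plus query-side and key-side
content-dependent positional biases, a global content bias and a global
positional bias, with trainable per-head vectors $u, v$. The layer output is

$$
\mathrm{out}_i \;=\; \sum_j \mathrm{softmax}_j\!\left(\frac{e_{ij}}{\sqrt{d_z}}\right)
\left( x_j W^V + b^V_{ij} \right).
$$

Both bias projections $b^K_{ij} = \phi_K(b_{ij})$ and
$b^V_{ij} = \phi_V(b_{ij})$ are two-layer networks with a hidden layer shared
across heads and per-head output slices; $\phi_K$ and $\phi_V$ have
independent parameters. Note that the two content-dependent bias terms share
the single projection $b^K_{ij}$; some of the relative-attention literature
uses distinct query- and key-side projections, but the shared form is what
this model defines, and we implement it as such.

Each encoder block applies the attention sublayer and a position-wise
feed-forward network (two linear layers with a leaky-ReLU between them). The
encoder uses pre-norm residual blocks (layer normalization before each
sublayer, plus a final normalization): the method description specifies the sublayers but
not the residual/normalization placement, so we adopt the arrangement that is
standard transformer practice and train most stably at small scale. The
leaky-ReLU negative slope is 0.1 everywhere; no slope is prescribed, and the
exact value only matters for being nonzero.

## The relation embedding

$b_{ij}$ concatenates three channels, in fixed order, with total width
$D' = (\texttt{max\_order} + 2) + 7 + \texttt{n\_emb}$:

1. **Neighborhood order** (one-hot, 6 classes by default): self, bonded, one
   atom between, two atoms between, three-or-more between, and a dedicated
   class for any pair involving the dummy node. The dummy class takes
   precedence over the others (the class list itself does not state a
   precedence; without it the "self" pair of the dummy node would be
   ambiguous). `max_order_variant()` collapses distant classes into the top
   bucket and shrinks the one-hot, mirroring the method's ablation of the
   maximum neighborhood order.
2. **Bond features** (7): one-hot bond order over $\{1, 1.5, 2, 3\}$,
   aromaticity, conjugation, ring membership; all zeros for non-bonded pairs
   (including every dummy pair).
3. **Distance embedding** (`n_emb` = 64 by default): the sine radial basis
   $e_n(d) = \sqrt{2/c}\,\sin(n\pi d/c)/d$ multiplied by the degree-$p$
   polynomial envelope
   $u(d) = 1 - \tfrac{(p+1)(p+2)}{2}x^p + p(p+2)x^{p+1} - \tfrac{p(p+1)}{2}x^{p+2}$,
   $x = d/c$, $p = 6$, which satisfies $u(0)=1$ and $u(c)=u'(c)=0$ so the
   embedding vanishes smoothly at the cutoff.

Numerical choices in the distance channel: the diagonal $d = 0$ uses the
analytic limit $\sqrt{2/c}\,n\pi/c$ rather than being zeroed, so self-pairs
carry a finite signature (the method description leaves the diagonal open); values are
exactly zero for $d \ge c$.

The cutoff defaults to $c = 20$ Å. It must exceed every intra-molecular
distance because the artificial **dummy node** — one extra atom appended to
each molecule, bonded to nothing — sits at distance $c$ from all real atoms,
i.e. exactly at the boundary where the distance embedding vanishes. The dummy
node has its own atom-type slot and its own neighborhood class, and gives
attention heads a "nowhere" position to park weight on.

Ablation switches (`use_neighborhood`, `use_bond`, `use_distance`) zero a
channel without changing $D'$, so ablated and full models are architecturally
identical.

## Atom features

Atoms are embedded as an $N_{\mathrm{atom}} \times 36$ matrix. The exact
composition of the 36 columns is not part of the method description; the package uses a documented
stand-in that preserves the printed total and the one-hot structure:
atom type over {B, N, C, O, F, P, S, Cl, Br, I, dummy, other} (12), heavy
degree 0–5 (6), formal charge −2..+2 (5), attached hydrogens 0–4 (5),
ring-size flags 3–6 (4), aromaticity (1), ring membership (1), a mask flag
used by pretraining (1) and one reserved zero column. Hydrogens are implicit
throughout — carbon dioxide is a 3-atom molecule — matching the heavy-atom
reading of `C(=O)=O`.

## Readout and descriptors

Self-attention pooling compresses the hidden states:
$P = \mathrm{softmax}(W_2 \tanh(W_1 H^\top))$ row-wise over unmasked atoms,
$g = \mathrm{flatten}(P H)$, so each of the $S$ pooling heads selects its own
soft subset of atoms and $g$ has length $S \cdot D$. (The method's notation
overloads one symbol for both the pooling-weight matrix and the pooling
hidden dimension; here they are `P` and `pool_dim`.) A two-layer MLP with
leaky-ReLU makes the prediction; optionally a block of 200 physicochemical
descriptors — the toolkit's canonical descriptor list ordered alphabetically
and truncated to 200, z-normalized with train-fold statistics, non-finite
values replaced by 0 — is concatenated to $g$ first. The descriptor block
bypasses the encoder entirely.

## Pretraining tasks

Two desk-scale self-supervised objectives, run sequentially:

1. **Contextual property prediction.** A fraction (default 0.15, with a
   floor of one atom) of real atoms is selected; the selected atoms *and all
   their bonded neighbors* have their atom features replaced by a mask vector
   (the dedicated mask column; the relation tensor is left untouched, and the
   dummy node is never masked). The model classifies each selected atom's
   radius-1 environment key — element plus the sorted multiset of
   `bondOrder-neighborElement` terms, e.g. `C_D-O2` for the carbon of CO2 —
   with a linear head on the final hidden state. The context radius is fixed
   at one hop and the vocabulary keeps every key seen at least `min_count`
   times (default 1 at this scale), with an explicit unknown class.
2. **Graph-level prediction.** Regression of a normalized physicochemical
   descriptor vector from the pooled embedding.

Masks are redrawn every presentation; given the seed, the whole procedure is
deterministic.

## Fine-tuning protocol, splits and metrics

`finetune()` implements the learning-rate-only protocol: the grid (default
$\{10^{-5}, 5\times10^{-5}, 10^{-4}, 5\times10^{-4}, 10^{-3}, 5\times10^{-3},
10^{-2}\}$ — seven values; the grid's members are not part of the method description, so
the default is a log-spaced stand-in and fully configurable) is searched per
split seed, the best rate is chosen on the validation fold, and the test fold
is evaluated exactly once per seed; the returned audit trail proves the test
fold never informs selection. Regression labels are z-standardized on the
train fold only. The optimizer is Adam with linear warmup (10% of steps) then
a constant rate; schedules beyond this are out of scope. Divergent grid
points (non-finite loss or gradients, or numerical overflow in a forward
pass) are recorded and skipped.

Scaffold splitting groups molecules by Bemis–Murcko scaffold, sorts groups by
size (descending, ties by first occurrence) and fills test, then validation,
then train, to their target counts — so structural analogues never span
folds. All acyclic molecules share the empty scaffold and therefore one
group. Metrics are RMSE and MAE for regression and ROC AUC for
classification.

## What the fixture generator emulates — and what it does not

`generate_fixtures()` assembles valence-valid SMILES from a fragment grammar
(aromatic and aliphatic ring cores, heteroatom chains, carbonyl/hydroxyl/
halogen branches), capped at 12 heavy atoms by default, always starting with
carbon dioxide. Labels include graph-only targets (heavy-atom count, ring
count, bond-order sum) and a geometry target $\sum_{i<j} 1/d_{ij}$ that
specifically exercises the distance channel. The generator emulates the
*structure* of small drug-like molecules — realistic valences, aromatic
systems, 3D conformers — but not the label noise, activity cliffs, assay
artifacts or size range of real benchmarks; passing the learnability tests
shows the architecture can extract graph and geometry signal end-to-end, not
that it reaches reported benchmark accuracy, which requires large-scale
pretraining and real datasets and is out of scope here.

Conformers are single UFF-optimized embeddings (deterministic given the
seed); flexible molecules are represented by one sampled conformation by
design. If embedding fails, coordinates fall back to a classical-scaling
layout of the hop matrix with bonded atoms near 1.5 Å and the molecule is
flagged (`coord_fallback`) so tests can exclude it; embedding failure
handling is a package choice. Multi-fragment inputs keep the largest
fragment with a warning.

## Problem sizes used by the test suite

The suite trains the reduced configuration (`rmat_small_config()`: 2 layers,
2 heads, $D = 32$) rather than the production-scale one: 300 fixtures /
50 epochs for the heavy-atom-count smoke test, 300 fixtures / 30 epochs /
3 seeds for the distance-ablation comparison, and 200 fixtures / 30 epochs
for the contextual pretraining check. These sizes are the smallest at which
the heavy-atom learnability and pretraining claims are stable across seeds;
see the caveat above for the ablation comparison.

One caveat the suite itself exposes: on these fixtures the *distance
ablation* does not reliably favor the distance-enabled model. Because a
single UFF conformer is a deterministic function of the molecular graph (and
the embedding seed), the geometry target $\sum_{i<j} 1/d_{ij}$ is almost
graph-determined (its correlation with the heavy-atom count alone is 0.98),
so the graph-only variant is a strong competitor; the dense per-pair
distance embeddings, meanwhile, act as molecule-specific fingerprints that
a few hundred training molecules allow the attention biases to memorize
(low train error, elevated test error). The suite runs the comparison and
asserts the distance-favoring direction; at this corpus size the assertion
can fail even though the distance channel demonstrably reaches the encoder
(coordinate perturbations change the pooled embedding, and rigid motions do
not). Demonstrating a robust distance advantage needs targets whose geometry
varies independently of the graph — e.g. conformer ensembles — which is out
of scope here.

## Known limitations

* E(3)- and reflection-invariant by construction (only interatomic distances
  enter), hence blind to enantiomers — a property the test suite asserts
  rather than fights.
* Attention is quadratic in molecule size; the implementation targets small
  to medium molecules.
* One conformer per molecule; conformer ensembles are out of scope.
* Stereochemistry-aware features, learned distance bins and charge-derived
  electrostatics are deliberately not implemented.
* The gradients are hand-derived (no autodiff); they are verified against
  central finite differences across every parameter group in the test suite.
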