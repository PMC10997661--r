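---
title: "Multiple molecular graph representations with attention readout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple molecular graph representations with attention readout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Why several graphs of one molecule

A small molecule has a natural graph: heavy atoms as nodes, bonds as
edges. Graph neural networks trained on this *atom graph* see topology at
its finest grain, but they must spend message-passing depth to discover
that six particular carbons form an aromatic ring or that a C(=O)O triple
is a carboxylic acid — chemistry a practitioner reads off instantly. The
package therefore builds, alongside the atom graph **A**, three *reduced*
graphs whose nodes are contracted subgraphs of the molecule:

* **P (pharmacophore)** — an ErG-style reduction. Each smallest ring
  collapses to one node (typed aromatic if fully aromatic, hydrophobic if
  a carbocycle); acyclic atoms with pharmacophoric character become typed
  nodes carrying a multi-hot over the six classes *H-bond donor, H-bond
  acceptor, positive, negative, hydrophobic, aromatic*; maximal acyclic
  carbon chains of three or more untyped atoms collapse to one
  hydrophobic node. Atoms with no assignable type remain as untyped
  "linker" nodes so that connectivity is never broken — the alternative
  (deleting them) would fragment the graph and lose topology.
  The SMARTS definitions behind the four pattern-driven classes ship in
  `inst/extdata/pharmacophore_features.yaml` and can be replaced.
* **J (junction tree)** — clusters are the smallest set of smallest
  rings, the non-ring bonds (atom pairs), and any atom shared by three or
  more clusters (a junction atom, which becomes its own node). Cluster
  links are resolved to a maximum spanning tree per connected component
  (shared-atom count as weight, junction links strongly preferred), which
  *guarantees* the result is a tree or forest. Acyclicity is not an
  empirical observation here but a construction invariant, and the test
  suite still verifies it exhaustively on generated molecules.
* **F (functional group)** — a shipped vocabulary of ~40 functional-group
  SMARTS (`inst/extdata/functional_groups.yaml`) is matched greedily,
  largest pattern first, ties by vocabulary order, without overlaps; then
  rings not yet covered become ring nodes, remaining bonds become
  atom-pair nodes, and leftover isolated atoms singleton nodes. Every
  heavy atom is covered by at least one node. No finite vocabulary covers
  all of chemistry; the fallback layers exist precisely so the graph is
  total anyway.

Every reduced node records `atom_map`, the set of atom indices it covers.
That map is load-bearing twice: for *initial pooling* (below) and for
projecting attention back onto atoms.

Reduced graphs carry no edge features (their edges assert adjacency
only); the atom graph carries bond-type/conjugation/ring edge features.
Pharmacophore edges are unweighted — the ErG lineage sometimes keeps
topological-distance weights, but an unweighted adjacency keeps the four
representations structurally interchangeable for the shared backbone.
Canonicalization keeps stereochemistry annotations in the SMILES; node
ordering is fixed by canonical atom ranks, making graph construction
deterministic.

# The network

Each representation in a scheme (e.g. `A+J`) has its own encoder and
backbone — no weight sharing — and the scheme's molecule embeddings are
concatenated before the prediction head. Per graph with node features
$x_i$:

1. **Encoding.** $h_i^{(0)} = W_{enc} x_i + b$; atom-graph edge features
   are encoded once into per-node sums $e_i = \sum_{j \in N(i)} W_e
   x_{ij} + \deg(i)\, b_e$.
2. **Node embedding** (edge-aware GIN with gated updates), for $t = 1
   \dots T$:
   $a_i = h_i + \sum_{j\in N(i)} h_j + e_i$, then
   $g_i = \mathrm{ReLU}(W_g a_i + b_g)$, then
   $h_i \leftarrow \mathrm{GRU}(g_i, h_i)$.
   The GIN self-weight $\varepsilon$ is fixed at 0; the GRU already
   provides an adaptive mix of old and new state, which is what a
   trainable $\varepsilon$ would buy.
3. **Readout.** A virtual super node with state $s$ (initialized to the
   mean node embedding) attends over all real nodes for $R$ rounds:
   $z_i = \mathrm{LeakyReLU}(a^\top W_p h_i + b^\top W_p s)$,
   $\alpha = \mathrm{softmax}(z)$,
   $c = \sum_i \alpha_i W_p h_i$,
   $s \leftarrow \mathrm{GRU}(c, s)$.
   The final $s$ is the molecule embedding; the final round's $\alpha$ is
   the node attention used for interpretation. Attention is single-head
   on purpose: one weight per node is the interpretable object, and a
   multi-head variant would need an extra (undefined) combination rule.
   Virtual links are directional (real node to virtual node); the super
   node never broadcasts back, keeping node embedding and readout
   separable.
4. **Initial pooling.** In schemes containing A, each reduced node's
   input features are extended with the *sum* of the raw atom features
   over its `atom_map`, so the reduction never fully discards atom-level
   information.
5. **Head.** Concatenated embeddings pass through one hidden ReLU layer
   (optional dropout) to a scalar; a sigmoid gives class probabilities.

There is no deep-learning framework underneath. Forward and backward
passes are explicit matrix algebra over block-diagonal molecule batches
(sparse adjacency), with all gradients derived by hand and checked
against central finite differences at tolerance 1e-5 in the test suite.
Training uses Adam (default learning rate 1e-3; the synthetic-benchmark
driver uses 5e-3, which the small 32-dimensional models tolerate well)
with binary cross-entropy or mean-squared-error loss. Regression targets
are standardized on the training fold and predictions de-standardized
before computing RMSE. Minibatch composition is drawn once per fold from
the seeded RNG and reused across epochs: batches are pre-assembled
block-diagonal graphs, and re-shuffling every epoch would rebuild them
for a negligible stochastic benefit. Everything downstream of the master
seed is bitwise reproducible on CPU.

Defaults: embedding width 256; message-passing rounds 2 for the atom
graph and 1 for reduced graphs (coarser graphs need fewer hops to cover
the same chemistry); 2 readout rounds.

# Training protocol and ranking

Datasets are sanitized (unparseable SMILES, bond-less and single-atom
molecules dropped; canonical-SMILES duplicate groups collapsed, removed
entirely when their targets disagree — for regression, "disagree" means
differing by more than 1e-9), split 8:2 into train+validation and test,
and the non-test part partitioned into 5 cross-validation folds. The
split is random, not stratified. One master seed drives the split, the
fold assignment, and the per-fold model seeds (seed + fold index).

Each fold trains up to 300 epochs, stopping after 30 epochs without
validation improvement (an improvement must exceed 1e-5 — a tolerance
the monitored metrics cannot meaningfully beat by less), restores the
best-validation weights, and evaluates the *shared* test set; the
reported performance is the mean of per-fold test metrics (AUROC for
classification, RMSE for regression). An ensemble of fold models would
be a legitimate alternative reading; the per-fold mean is what the
package reports.

`summarize_model_ranking()` condenses a models-by-datasets metric table:
per dataset, models are ranked (ties share the mean rank) and z-scored
against the across-model mean and standard deviation, signs flipped for
lower-is-better metrics. The z-score uses the sample (n−1) standard
deviation by default — with the typical four models per dataset the
distinction matters — and a population option is exposed.

# From attention to interpretation

The extraction order is fixed and matters:

1. raw virtual-link attention per graph (a distribution over nodes);
2. min-max normalization to [0, 1] per graph;
3. projection onto atoms: each atom receives the *sum* of the attention
   of every node covering it (overlaps add; uncovered atoms get 0),
   then the atom vector is min-max normalized again;
4. for multi-graph schemes, the elementwise *maximum* across the mapped
   atom vectors.

A constant vector has no min-max image; it maps to 0.5 everywhere
(neutral importance) rather than 0 or 1, so a degenerate readout neither
hides nor fabricates signal. For 5-fold visualizations the per-fold
combined vectors (each normalized within its fold) are averaged
arithmetically; normalizing after averaging would let one fold's scale
dominate, which is why normalization happens per fold.

Three views consume these vectors. The *single-prediction view* renders
per-atom green intensity plus a JSON dump. The *node-features view*
accumulates, over a (optionally prediction-filtered) molecule set, the
per-graph normalized attention of every node against each of its active
indicator features — multi-hot nodes contribute to every active feature
name — and plots mean attention against occurrence count. It uses the
per-graph attention on the reduced graph's own nodes, not the combined
atom vector, because the features being summarized are reduced-node
features. The *potential-substructures view* is described next.

# Fragment mining and the importance score

Molecules are fragmented three ways and the results pooled: BRICS bonds
(all cleaved simultaneously), RECAP bonds (the eleven classical
retrosynthetic bond environments, shipped as SMARTS in
`inst/extdata/recap_rules.yaml`, all cleaved simultaneously), and an
exhaustive cutter that severs every single acyclic bond and every pair of
acyclic bonds. Only acyclic bonds are ever cut — rings stay intact by
construction — and pieces outside 3–20 atoms are discarded. Fragments
are deduplicated by atom set within a molecule and aggregated across
molecules by canonical fragment SMILES.

A fragment occurrence is *important* when the median attention of its
atoms strictly exceeds the $P_f$ percentile (default 75, linear
interpolation) of the molecule's atom attention. Per fragment type, with
$N_{frag}$ occurrences, mean fragment attention $M_{frag(n)}$ and mean
molecule attention $M_{mol(n)}$ for occurrence $n$:

$$\mathrm{Score}_{frag} = \frac{1}{N_{frag}} \sum_{n=1}^{N_{frag}}
\left(M_{frag(n)} - M_{mol(n)}\right).$$

$M_{mol}$ averages over *all* atoms of the molecule, the literal reading;
averaging over non-fragment atoms only would inflate scores of large
fragments. A fragment becomes a *potential substructure* when (i) its
important-compound percentage is at least 50%, (ii) its important-compound
count reaches the $P_s$ percentile (default 70) of those counts across
all fragments, and (iii) its score is strictly positive. Redundancy is
then removed: a kept fragment that is a subgraph of another kept fragment
with an equal-or-higher score is dropped, so the larger context wins
unless the smaller fragment genuinely scores better. Containment is
decided on occurrence atom sets within shared molecules, which is exact
for fragments of the same molecule and avoids a SMARTS round-trip.

# Synthetic binding logics and attention metrics

Five built-in logics label a molecule positive iff a boolean combination
of SMARTS patterns matches: fluorine AND carbonyl; an unbranched acyclic
three-atom chain AND carbonyl; primary amine AND dialkyl ether AND
mono-substituted benzene; (dialkyl ether OR no hydroxyl) AND carbonyl AND
no internal alkyne; and any three-membered ring. For positives, every
combination of one match per matching ground-truth pattern yields an
alternative mask (the union of the matched atoms), capped at 32
combinations — beyond that the max over alternatives is numerically
saturated anyway. Patterns under NOT contribute no mask atoms: an
absence has no atoms to highlight.

The generator assembles molecules from a fragment grammar (chain, branch
and ring units, 8–25 heavy atoms — the typical drug-like range), inserts
or withholds each logic's pattern pieces to steer the class balance
toward 50/50, and always relabels by exact logic evaluation, so labels
are correct by construction even when insertion misfires. What it does
*not* emulate: the size, scaffold diversity and property distributions of
real screening collections, activity cliffs, label noise, or assay
artifacts. A model passing these benchmarks demonstrably routes attention
to the causally relevant atoms of a clean, known mechanism; that is
evidence about the interpretation machinery, not a claim about
performance on pharmaceutical endpoints.

Attention quality is scored on true positives (label 1, predicted
probability at least 0.5) with two metrics, each maximized over the
alternative masks. *Attention AUROC* treats the combined atom attention
as a scorer of mask membership (computed by the Mann-Whitney rank
formula; ties receive average ranks, so a uniform vector scores exactly
0.5). *Attention accuracy* is

$$\mathrm{AttACC} = \frac{1}{N} \sum_{i=1}^{N} I(y_i - \bar y_i),$$

where $\bar y_i = 1$ iff the attention of atom $i$ is at least 0.5 and
$I(x) = 1$ iff $x = 0$; thresholding is applied to the final combined
normalized vector (thresholding per fold before normalization is a
defensible alternative; one convention is used consistently). Masks
covering no atom or every atom leave AUROC undefined and are skipped.

# Problem sizes, numerical choices, limitations

The shipped end-to-end benchmark (`run_logic_experiment()`, also driven
by `scripts/acceptance.R` and exercised in the test suite) uses 2000 generated
molecules of the three-membered-ring logic, 32-dimensional embeddings, a
single trained fold of a 5-fold split, and at most 50 epochs — sizes at
which the full pipeline, including fragmentation, runs comfortably on one
CPU while still showing the qualitative pattern of interest: test AUROC
above 0.9 and attention AUROC well above chance for both the atom-graph
and atom+junction-tree schemes. The full 256-dimensional, 5-fold, 300-
epoch protocol is the package default for real datasets.

Other numerical conventions collected in one place: percentiles use
linear interpolation (R type 7); the importance rule is a strict
inequality while the support rule is non-strict, mirroring the stated
selection conditions; attention ties in AttAUROC get average ranks;
predicted-positive thresholds are 0.5; salts and multi-fragment SMILES
are kept (flagged in the load log) since deleting counter-ions silently
would alter targets' meaning; `[Na+]`-style single-atom entries are
dropped. Known limitations: the functional-group vocabulary is finite
and greedy matching is order-dependent (largest-first is a heuristic,
not an optimum); the pharmacophore typing SMARTS are deliberately
compact and catch the common cases, not tautomer-aware edge cases; the
exhaustive fragment cutter stops at two simultaneous cuts, so very
large multi-domain fragments can be missed; and attention is an
explanation of the model, not of the chemistry — a model can be right
for the wrong atoms, which is exactly what the synthetic benchmarks are
there to measure.
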