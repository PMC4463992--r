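---
title: "Radial-shell protein similarity and signed-network pathway ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-shell protein similarity and signed-network pathway ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialsim)
```

## The problem

p42.3 is a mitosis-dependent protein implicated in gastric carcinogenesis.
Its sequence carries an EF-hand calcium-binding motif and a coiled-coil
domain — the same combination found in the S100 family — but its regulatory
role is unresolved. The strategy implemented here infers candidate
regulation indirectly: score the structural/compositional similarity of
p42.3 against reference proteins that share its domains and are linked to
cell proliferation, use those scores as prior activation probabilities of
the reference proteins in a signed regulatory network ending at a "cell
proliferation" sink, and report the root-to-sink pathway with the maximum
propagated probability.

The similarity metric is deliberately alignment-free: no superposition,
no RMSD, no sequence alignment. It compares summary statistics of the two
structures, the dominant one being the radial distribution of atoms around
the geometric center.

## The nine-parameter similarity

For an ordered pair (query $q$, target $t$) read from PDB coordinates
(`read_structure()`), nine similarities are computed:

1. **Shell-density similarity ($S_1$).** Atoms are binned by their distance
   from the geometric center into 10 concentric shells with boundaries at
   10, 20, ..., 80, 100 length units, the tenth shell open-ended
   (`default_layer_scheme()`). With per-shell counts $l_{qi}, l_{ti}$ and
   totals $n_q, n_t$:
   $$\mathrm{sim}_i = 1 - \frac{|l_{qi} - l_{ti}|}{l_{qi}}, \qquad
     w_i = \frac{1}{2}\left(\frac{l_{qi}}{n_q} + \frac{l_{ti}}{n_t}\right),
     \qquad S_1 = \sum_{i=1}^{10} w_i\,\mathrm{sim}_i .$$
   The weights sum to 1, so shells holding more mass dominate the score.
2. **Scalar similarities ($S_2$–$S_7$).** Atom count, residue count,
   residue-type count, and C/N/O atom proportions each scored as
   $1 - |n_q - n_t|/n_q$ (`scalar_similarity()`).
3. **Sparse-element position ($S_8$, $S_9$).** P and S are too scarce for
   count comparison; instead their shells are compared: same shell 1.0,
   adjacent shells 0.8, otherwise 0 (`element_position_similarity()`).

The overall score is the plain dot product $S = \sum_i Q_i S_i$ with the
packaged trained weights (`table1_weights()`), which sum to 1.0007 — a
structure scored against itself therefore reports 1.0007, not 1, and the
package preserves that.

### Conventions the formulas leave open

* **Asymmetry.** Every denominator is the query's value, so
  $S(q,t) \ne S(t,q)$ and scores can be negative (the packaged reference
  table contains entries down to $-1.78$). This is intentional and is
  documented rather than symmetrised: the reference table could only have
  been produced by the unsymmetrised form.
* **Empty query shells.** $\mathrm{sim}_i$ is undefined when $l_{qi} = 0$.
  The package scores 1 when both shells are empty and 0 otherwise, the only
  choice that keeps self-similarity exactly 1 while staying bounded above.
* **Half-open shells.** Shell $i$ is $[b_{i-1}, b_i)$; a radius exactly on
  a boundary belongs to the outer shell, so every radius maps to exactly
  one shell.
* **Several P/S atoms.** The positional rule is stated for single atoms;
  with several, the best-matching cross-pair counts (optimistic
  best-match), which reduces to the stated rule for single atoms. Both
  structures lacking the element scores 1.0 — the packaged reference table
  shows full P-similarity for a query with no phosphorus — and exactly one
  lacking it scores 0.
* **Units.** Shell boundaries are interpreted in the coordinate file's
  native length unit (ångströms for PDB). The numeric boundary values are
  used as printed; a protein of radius 80 nm would be physically
  implausible, and PDB files are in Å, so the printed numbers are kept and
  the unit follows the file.

## Weight fitting

The nine weights were originally obtained by back-propagation training on
pairs labelled with an external homology score. Because the published
combination rule is an intercept-free linear form, the default trainer
(`train_weights()`) is a single linear unit without bias trained by
full-batch gradient descent on mean squared error — back-propagation's
delta rule, on a convex problem, so it converges to the least-squares
solution. Defaults: learning rate 0.3 (stable for features on the
$[-0.5, 1]$ scale, whose Hessian's largest eigenvalue is well below the
$2/\eta$ stability bound), at most 20\,000 epochs, early stop when the
loss change drops below $10^{-15}$. Starting from zeros makes the linear
fit deterministic with no seed dependence; shuffling rows cannot change a
full-batch fit. No non-negativity or sum-to-one constraint is imposed —
the published weights sum to 1.0007, so none was imposed originally
either. A one-hidden-layer network (sigmoid hidden units, linear output,
seeded random initialisation) is provided for fidelity to the "neural
network" description but is not the default; its extra capacity buys
nothing on a linear labelling and costs identifiability.

The original training pairs (homology-labelled) are not reproducible
offline, so the generator replaces them: `make_training_set()` draws
features uniformly in $[-0.5, 1]$ — matching the observed range of real
parameter similarities, negatives included — and labels them with a known
weight vector plus Gaussian noise. The default size of 100 pairs mirrors
the original training collection.

## Signed-network propagation

The regulatory network is a DAG with activating (`+`) and inhibiting
(`-`) edges and a designated sink (`build_network()`). Source nodes
(in-degree 0, sink excluded) take their protein's overall similarity as
prior activation probability, clamped into $[0,1]$ with a logged
diagnostic (`set_priors()`).

The published account gives the Bayesian-network factorisation but never
the conditional tables; only one combination formula is printed, with
undefined symbols, and read literally it over-counts: for inhibiting
parents $A, B$ and activating parents $C, D$ it sums
$P(\bar A \bar B C) + P(\bar A \bar B D) + P(\bar A \bar B C D)$, which
exceeds 1 for strong activators. The package therefore provides two modes
(`propagate()`):

* **union** (default): the coherent reading —
  $$P(v) = \prod_{u \in \mathrm{inh}(v)} (1 - P(u)) \cdot
    \Big(1 - \prod_{u \in \mathrm{act}(v)} (1 - P(u))\Big),$$
  noisy-OR over activators gated by the complement of every inhibitor.
  It stays in $[0,1]$ for any priors and, on networks where each node's
  parents have disjoint source ancestries (trees), equals the exact
  probability that at least one activating parent fires and no inhibiting
  parent fires under independent Bernoulli sources — the package's tests
  verify this by exhaustive enumeration. On DAGs with shared ancestors the
  rule is an independence approximation.
* **literal**: the printed sum (each activator singly, plus the full joint
  activator term, all gated by the inhibitor complements), clamped at 1
  with a message, kept for comparison with the original account.

`path_probability()` scores one root-to-sink chain in isolation: the root's
prior is carried along the chain, an activating edge passing it unchanged
and an inhibiting edge replacing it by its complement; an all-activating
chain therefore delivers exactly its root's prior.
`rank_pathways()` enumerates every simple source-to-sink path (via igraph)
and orders them by that probability, ties broken lexicographically so the
ranking is deterministic and independent of edge order.
`posterior_attribution()` inverts the propagation: each source's
contribution to a node is the node's union-mode probability when only that
source keeps its prior, normalised over sources.

## The packaged tables and the reconstruction

Two published tables ship verbatim under `inst/extdata/`: the nine trained
weights and the 17-row reference-protein similarity table. Two
inconsistencies in the latter are preserved, not corrected: its own header
prints 0.020 where the weight table prints 0.0204 (the weight table is
taken as canonical), and its printed overall column does not equal the dot
product of its printed rows with the weights (S100A11: printed 0.8102,
recomputed 0.8328). Recomputation still ranks S100A11 first, which is the
fact the pathway stage depends on.

The curated network topology behind the original analysis was never
printed, so the packaged network
(`example_network_edges_synthetic.tsv`) is an illustrative reconstruction,
labelled synthetic: it contains the reported winning chain
S100A11 → RAGE → P38 → MAPK → microtubule-associated protein → spindle
protein → centromere protein → cell proliferation, a competing RASEF-rooted
chain through the Ras/Raf-1/MEK cascade, a GCN4 transcription-activation
chain, an inhibiting FKBP edge onto P38, CENP-B feeding the centromere
node, and S100A2 as a direct inhibitor of proliferation. With the published
similarities as priors the S100A11 chain ranks first at 0.8102. The
originally reported top-path probability (0.9781) depends on the unprinted
full topology and prior assignment and is not reproducible from printed
information; the package makes no attempt to match it.

## The synthetic generator

`make_structure()` emulates exactly the statistics the metric reads —
radial shell occupancy, element composition, residue bookkeeping — and
nothing else. Atoms are sampled shell by shell: planned integer per-shell
counts (largest remainder), radii uniform within each shell but at least a
margin (0.25–0.5 units) away from the boundaries, directions uniform on
the sphere. Because the metric centers structures at their own geometric
mean, the cloud is then recentred by alternately subtracting the mean and
restoring each atom's planned radius; this converges to a residual center
offset around $10^{-10}$, orders of magnitude below the sampling margin,
so the planned shell counts are recovered *exactly* by `layer_profile()`.
The last, open-ended shell is sampled within 15 units above its lower
bound. `pin_elements` places all atoms of an element in a chosen shell,
which is how the P/S positional rule is staged in tests.

What the generator does **not** emulate: bond lengths, sterics, secondary
structure, realistic residue compositions, crystallographic artifacts
(altlocs, partial occupancies, missing atoms). Tests passing on generated
structures therefore validate the arithmetic of the metric and pipeline,
not its biological discriminative power on real structures.

`make_network()` builds parallel source-to-sink chains with optional
crossing edges into strictly deeper layers (acyclic by construction). The
planted source gets prior 0.9 and an all-activating chain; competitor
priors are drawn from $[1 - 0.9 + 0.05,\; 0.9 - \mathrm{margin}]$ (default
margin 0.4). Keeping competitor priors above $1 - 0.9$ matters: a path
through an odd number of inhibiting edges carries the *complement* of its
root prior, and the lower bound caps that complement below the planted
prior, making the planted chain the unique maximum for every seed.

## Problem sizes and runtime choices

The shipped tests compare every layer quantity against independently coded
brute-force recomputations on 100 random structure pairs of 50–1500 atoms,
verify propagation against exact $2^k$ Bernoulli enumeration on 30 random
source trees with up to 6 sources, and check planted-pathway recovery on
50 seeded networks; the full suite runs in well under a minute. These
sizes were chosen to exercise every code path at the scale of real
single-domain proteins (a few hundred to a few thousand heavy atoms)
while keeping the suite quick to run during development.

## Known limitations

* The similarity is a bag-of-statistics score: structures with identical
  radial profiles and compositions but different topology are
  indistinguishable. That is a property of the method, not of this
  implementation.
* The union rule assumes parent independence; on DAGs where two parents
  share an ancestral source it is an approximation (exact on trees).
* The asymmetric denominator makes scores unbounded below for targets much
  larger than the query; ranking is unaffected, but absolute values should
  be read with the query fixed.
* PDB parsing keeps the first model and the first alternate location;
  occupancy-weighted handling is out of scope.
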