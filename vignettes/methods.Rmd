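---
title: "Fragment-wise molecular optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-wise molecular optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

moltree optimizes a given small molecule against an arbitrary evaluation
function by editing its graph fragment by fragment. This vignette is the
package's own account of the method: the two nested tree searches, the
neural generator that proposes fragments, the scoring functions, the
numerical choices, and what the bundled synthetic fixtures do and do not
demonstrate.

## The molecule representation

Molecules are hydrogen-implicit, kekulized, neutral 2-D graphs
(`mol_graph`): atoms are indices into a fixed nine-element vocabulary
(C, N, O, F, P, S, Cl, Br, I — the conventional heavy-element set of
drug-like screening collections), bonds carry order 1, 2 or 3, and
aromatic rings are always stored as alternating Kekulé single/double
bonds, so no aromatic bond type exists anywhere in the model. Valence
accounting is purely heavy-atom: an atom's free valence is its element's
maximum valence (C 4, N 3, O 2, F 1, P 5, S 6, Cl 1, Br 1, I 1) minus
its bond-order sum, and every open unit is an implicit hydrogen.
Stereochemistry, formal charges, isotopes and 3-D coordinates are out of
scope; charged and stereo-annotated SMILES are stripped on input and
rejected if the neutral form violates valence. Parsing, kekulization and
canonical SMILES come from OpenBabel; canonical SMILES doubles as the
identity key for all deduplication.

## The outer search: editing by fragments

`optimize_molecule()` runs a Monte Carlo tree search whose nodes are
complete molecules, rooted at the seed. Each cycle:

1. **Selection.** Descend from the root by the UCB1 rule
   `xbar + c * sqrt(2 log n_parent / n)` with `c = sqrt(2)` by default;
   unvisited children score `Inf` and are taken first.
2. **Expansion.** The selected leaf gains two kinds of children.
   *Removals*: for every acyclic single bond whose deletion splits the
   molecule, the connected component with more atoms becomes a child
   (ties keep the component whose canonical SMILES sorts first —
   determinism is the only reason). *Additions*: the inner atom-wise
   search grows a fragment at one uniformly chosen free-valence atom and
   returns scored candidate molecules; with probability `1 - epsilon`
   the top `m_add = 5` by score are kept, otherwise `m_add` at random
   (`epsilon = 0.2`).
3. **Evaluation.** Children are scored directly by the evaluation
   function. There is no rollout at this level: a molecule has no
   natural terminal state (the seed is already a complete molecule), and
   every child is itself a finished candidate.
4. **Backpropagation.** The *maximum* squashed child reward is added to
   every node on the root path and each visit count increments by one.

Because additions attach fragments through single bonds and removals cut
single acyclic bonds, ring systems are never edited directly; every
node of the tree is a valid molecule by construction, which is the
method's structural headline (validity = 1).

A protected substructure (`protect =`) is matched as an exact colored
subgraph (elements + bond orders, VF2); removal children that lose it
are discarded. This is subgraph matching, not SMARTS.

## The inner search: growing one fragment

`run_atom_search()` builds the fragment atom by atom, one atom per tree
node, starting from the empty state. Expansion queries the generator for
the `k = 5` most probable valence-masked (atom, bonds) continuations;
the stop label may be among them, giving a terminal child whose fragment
is the current partial state. The best new child is completed to
termination by temperature-1 sampling (rollout) under the same masks,
capped at 15 atoms — the corpus fragments average ~5 atoms with an upper
tail near 10, so the cap is generous without letting rollouts wander.
A state is terminal when the model emits the stop label or predicts no
bond for the new atom. The completed fragment is attached to the parent
molecule by a single bond from the fragment's first generated atom
(whose valence keeps one unit in reserve throughout generation so the
attachment bond always exists) to the site chosen by the outer search,
and the evaluation of that *attached molecule* — never of a partial
state — is squashed and backpropagated.

An empty fragment (immediate stop at the root) is a "no change" edit: it
backpropagates the parent's own squashed score and contributes nothing
to the results.

## The generator

The fragment proposals come from a three-part network trained on a
fragment corpus:

* **Encoder** — 6 layers of edge-conditioned message passing with one
  weight matrix per bond order plus a self term, symmetric
  degree-normalized (`1 / sqrt(d_i d_j)`), ReLU activations,
  128-dimensional node states, and sum pooling into a graph vector. A
  plain order-agnostic graph convolution is available as
  `model_config(flavor = "gcn")`. The empty state is served by a zero
  graph vector, so the first atom of a fragment is modelled too.
* **Atom head** — a two-layer MLP (64 hidden units, ReLU, softmax) over
  ten classes: the nine elements plus a stop label.
* **Bond head** — a two-layer GRU with 256-dimensional state,
  initialized from a linear map of `[Emb(atom label); h_g]` (64-dim
  embedding) passed through tanh, consuming the node hidden vectors in
  BFS order and emitting, per existing atom, a softmax over
  {single, double, triple, none} through a 64-unit ReLU output layer.

Training is teacher-forced: every corpus fragment is canonicalized and
serialized from atom 1 of its canonical ordering into `n + 1` steps
(state, next atom, bond labels), the bond head always consumes the label
atom, stop steps carry no bond loss, and the loss is the summed
cross-entropy of both heads, minimized by Adam (learning rate 1e-4,
batch 128 by gradient accumulation over steps, gradient norm clipped at
5, no schedule). Each fragment contributes one canonical serialization;
`build_training_steps(weighting = "source_count")` weights fragments by
their corpus frequency instead of uniformly. The reference protocol
trains 50 epochs and uses the epoch-20 parameters
(`snapshot_epochs = 20`); the bundled experiments train 20 epochs
directly, which is equivalent and cheaper.

The BFS root and tie-breaks (ascending atom index among equal-depth
frontier atoms; canonical atom 1 as root) are package conventions chosen
for reproducible training sequences — nothing in the method depends on
the particular deterministic choice.

At search time the model runs through a single-precision compiled
engine (`compile_generator()`); sampling is bandwidth-bound on the GRU
weight matrices, and the float path agrees with the double-precision
training path to ~1e-5 in probabilities, far below sampling noise. All
randomness is drawn from R's RNG, so any run is reproducible under
`set.seed()` / `rng_seed`.

## Building the training corpus

`fragment_molecule()` cuts every bond that joins a ring atom to a
non-ring atom (ring membership decided on the parent molecule: an atom
is in a ring if it touches any cycle edge) and returns the connected
components; molecules with no such bond pass through whole. Cut ends are
capped by implicit hydrogens, so every fragment is a plain valid
molecule — the generator therefore produces plain molecules, with no
attachment-point dummy atoms. `build_corpus()` aggregates fragments by
canonical SMILES with source counts and drops fragments above
`max_atoms = 25`.

## Evaluation functions

* **QED** (`qed_score`) — weighted geometric mean of desirability
  transforms of eight properties, using the published desirability
  parameters and mean weights. Descriptor sources: molecular weight,
  logP (Wildman–Crippen as implemented by OpenBabel), H-bond acceptors
  (N+O count) and donors, and topological polar surface area from
  OpenBabel; rotatable bonds (acyclic single bonds between non-terminal
  heavy atoms, without the amide exception) and aromatic rings (smallest
  rings through each cycle bond, aromatic when a Hückel-style electron
  count over ring doubles and heteroatom lone pairs hits 4n + 2) on the
  package's own graphs. The structural-alerts descriptor is **not**
  implemented (it needs a SMARTS engine); ALERTS is fixed at 0, which
  shifts QED slightly upward for molecules that carry alerts. On
  alert-free molecules this implementation reproduces the reference
  values exactly (e.g. benzene 0.443, caffeine 0.538, ibuprofen 0.822).
* **Penalized logP** (`penalized_logp`) — logP minus a synthetic
  complexity term minus a large-ring penalty (ring atoms beyond six in
  the largest smallest-ring), all unnormalized. The complexity term is
  a package heuristic (size, ring fusion, macrocycles, quaternary
  branching, on a 1–10 scale), monotone in each ingredient; it is *not*
  the fragment-contribution synthetic-accessibility score, which
  requires an external fragment-frequency database.
* **Similarity-constrained scores** gate any base score at an ECFP4
  Tanimoto threshold against the seed (default `delta = 0.4`),
  returning `-Inf` below it so constrained candidates are never
  selected. The fingerprint is a radius-2 Morgan construction folded to
  2048 bits, implemented in the package.
* Any R function from `mol_graph` to a finite number plugs in through
  `score_function()`; scores are cached by canonical SMILES and must be
  pure.

Rewards are squashed into [-1, 1] before backpropagation: linearly for
scores with a declared range (QED maps 0 -> -1, 1 -> +1), `tanh(x/10)`
for unbounded ones (penalized logP). `-Inf` squashes to -1.

## Study conditions and problem sizes

The package's reference experiments, used by the test suite and
`scripts/acceptance.R`, run at desk scale on one CPU:

* generator trained on the bundled synthetic corpus (500 molecules, 453
  distinct; 360 distinct fragments) for 20 epochs at the reference
  hyperparameters — a few minutes;
* unconstrained QED optimization of 10 seed molecules drawn from the
  corpus with QED in [0.6, 0.7], 20 fragment-wise x 100 atom-wise
  cycles per seed (the unconstrained preset; the constrained penalized
  logP preset is 2 x 100);
* a memorization check: 10 diverse fragments, 20 epochs at tiny-corpus
  settings (learning rate 2e-3, batch 4 — the reference batch of 128
  exceeds the corpus itself, so batch and rate are rescaled), after
  which at least 9 of the 10 fragments must reappear exactly among 2000
  temperature-1 samples. Exact *greedy* regeneration of all fragments
  is not a meaningful target: greedy decoding is deterministic from the
  shared empty state, and fragments that share a prefix (all do) cannot
  be distinguished by it.

## What the synthetic fixtures show — and what they do not

The bundled corpus is produced by `generate_fixture_corpus()`: ring
systems, substituents and linkers assembled at random through the
package's own attachment primitive, so validity is guaranteed by
construction and the gross composition (aromatic/saturated rings with a
few polar or halogen substituents, MW roughly 100–350) resembles
drug-like collections. It does **not** reproduce real-compound
diversity, functional-group co-occurrence statistics, synthesizability,
charge states or stereochemistry. Passing tests on these fixtures
demonstrate the mechanics — valence-safe generation, corpus round-trips,
search bookkeeping, score improvement — not medicinal-chemistry
performance on real libraries; headline numbers from full-scale corpora
(hundreds of thousands of molecules, hundreds of seeds) are outside the
desk-scale conditions.

## Numerical choices and degenerate inputs

* Removal ties (equal component sizes) keep the canonical-SMILES-first
  component; BFS ties visit ascending atom indices — determinism only.
* Unvisited children select first (`ucb1 = Inf`); among equal UCB1
  scores the first child wins.
* Bond sampling masks any order exceeding either endpoint's remaining
  valence, renormalizes, and treats an all-"none" draw as the terminal
  signal; masking guarantees no sampled graph ever violates valence.
* A seed that is a bare ring (no removable bond) expands through
  additions only; a seed with neither removable bonds nor free valence
  raises an error at the first cycle.
* Molecules whose canonical SMILES OpenBabel cannot produce (rare
  pathological fused cages emitted by weakly trained generators) are
  treated as unserializable no-ops during search: not scored, not
  collected.
* Training is deterministic given the seed; the compiled float engine
  is deterministic given the same build and platform.

## Known limitations

* No SMARTS: protected substructures are exact subgraphs; QED lacks the
  alerts term.
* The synthetic-complexity heuristic is a stand-in; penalized-logP
  values are internally consistent but not comparable to literature
  numbers computed with the fragment-based score.
* The generator conditions only on the growing fragment, not on the
  parent molecule it will be attached to — fragments are proposed
  context-free and selection pressure comes entirely from the scores.
* Single-threaded; the search is sequential by design (each cycle
  conditions on the tree built so far).
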