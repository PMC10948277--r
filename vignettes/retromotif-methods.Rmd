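---
title: "Motif-based autoregressive retrosynthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based autoregressive retrosynthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Single-step retrosynthesis asks: given a product molecule, which reactant
set could have produced it in one reaction? `retromotif` treats this as a
graph-generation problem with a fixed program structure. A product graph
$G_P$ with $n$ atoms and $m$ bonds is transformed into reactant graphs by a
*transformation path* of tokens:

* **Edit** tokens identify the reaction center: a bond edit retypes or
  removes a bond (new type in {none, single, double, triple}); an atom edit
  changes an atom's hydrogen count and/or formal charge. Applying the edits
  yields *synthons* — product fragments with open valences. The atoms
  touched by edits are the *attachment atoms*.
* **FinishEdit** closes the edit phase. The attachment atoms are queued in
  ascending entity order.
* **AddingMotif** tokens complete the synthons: each attachment atom
  receives one *motif* — a reactant subgraph carrying one or more
  *interface atoms*. The predicted interface atom is merged with the
  attachment atom; any further interface atoms of the motif are promoted to
  new attachment atoms and served depth-first before the remaining queue.
  Generation terminates structurally when the queue empties; no end-token
  is predicted.

Bonds and atoms share one entity index space: bonds occupy $[0, m)$ in
enumeration order, atoms $[m, m + n)$. The factored likelihood of a path is

$$P(G_R \mid G_P) \;=\; \prod_{t=1}^{N} P(\pi_t, o_t, \tau_t \mid o_{<t},
\tau_{<t}, G_{<t}),$$

with action $\pi_t$, object $o_t$ (an entity or a motif) and state $\tau_t$
(a bond type, an atom change, or an interface index).

## Motif extraction and the vocabulary

Motifs are extracted from mapped training reactions. Reactant atoms whose
map numbers occur in the product are synthon atoms; the rest are
leaving-group atoms. Three cutting rules apply:

1. every bond between a synthon atom and a leaving-group component is
   broken, and the motif keeps a *copy* of the synthon atom as its
   interface (element, charge and hydrogen count are retained, which makes
   the later merge exact);
2. a bond whose two endpoints lie in two different rings is broken
   (bonds *inside* a fused system lie on a ring themselves and are kept);
3. a bond between a ring atom and an out-of-ring atom of degree > 1 is
   broken.

Rules 2–3 are applied iteratively to a fixed point; each cut keeps the
parent-side endpoint as the child motif's interface and marks that same
atom as a new interface on the parent, so attaching the parent later
exposes the child's attachment site (the interface-to-attachment
promotion). An attachment atom with no leaving-group neighbours yields a
single-atom motif — just the interface copy — which is the vocabulary's
"complete with hydrogens" entry; this makes the junction tree total (every
attachment receives exactly one motif, also at decode time).

Motif identity is by *canonical key*: the canonical SMILES of the motif
graph with interface atoms carrying map numbers $1..K$ assigned in
canonical atom-rank order. The key round-trips: parsing it recovers the
graph and the interface ordering exactly, so the vocabulary file stores
keys only. Ids are positions in the radix-sorted key list — deterministic,
input-order- and locale-independent. No frequency cutoff is applied.

Canonicalization itself is delegated to OpenBabel (`obabel`), used as the
canonical-ranking engine throughout; its atom ranking is independent of
atom-map numbers, which the mapping-normalization step relies on. Calls
are batched (one process per corpus pass), which keeps preprocessing of a
few hundred reactions in the tens of seconds.

## Mapping normalization

Benchmark reaction sets leak information through atom-map numbering (the
atom mapped "1" tends to sit in the reaction center). `remove_dataset_shortcut()`
re-orders the product's atoms into canonical SMILES output order, renumbers
maps $1..n$ in that order on both sides, and freezes the bond enumeration
from the canonical form. The result is chemically identical, its numbering
carries no reaction information, and all entity indices are reproducible.

## Featurization

The atom vector has width 45: element one-hot over 16 symbols plus "other"
(17), degree 0–5 (6), formal charge −2..+2 (5), total hydrogens 0–4 (5),
chirality none/@/@@/other (4), hybridization s/sp/sp2/sp3/other (5, a
bond-order-derived proxy), aromatic flag (1), in-ring flag (1), and a
radical placeholder (1, always zero — radicals are not modelled). When the
reaction class (1–10) is supplied, a 10-wide one-hot is appended (55).
Bond vectors have width 12: order one-hot (4), conjugation (1), in-ring
(1), stereo/direction one-hot (6). Every bond also has a 4-wide one-hot
over {none, single, double, triple} for the edit-type head. This exact
layout is recorded in vocabulary files and checkpoints.

## Encoder and decoder

The encoder is an $L$-layer graph transformer over atoms: multi-head
self-attention restricted to bonded neighbours plus a self-loop, with bond
features projected into the attention keys (edge-feature bias), residual
connections and layer normalization, and a Mish feed-forward block.
Defaults are $D = 256$, $L = 4$, 8 heads; the compact setting used in this
package's own experiments is $D = 64$, $L = 2$, 4 heads. Entity embeddings
come from a shared two-layer Mish perceptron: $e_{uv} = \mathrm{MLP}(h_u
\,\|\, h_v)$ for bonds and $e_{uu} = \mathrm{MLP}(h_u \,\|\, h_u)$ for
atoms. The graph embedding $h_G$ is a gated-attention readout (score MLP,
softmax over atoms, weighted sum of projected atom embeddings), which makes
$h_G$ permutation invariant and the entity embeddings equivariant.

The decoder is a GRU with hidden state initialized by a linear map of
$h_G$ and first input $0$. At each step the context $\psi_t = h_G \,\|\,
u_t$ feeds five heads: a 3-class action head (Edit / FinishEdit /
AddingMotif — the start token is input-only and never predicted); a
per-entity edit score $\hat s_i = \sigma(\mathrm{MLP}(\psi_t \,\|\, e_i))$;
a type head conditioned on the selected entity, over 4 bond classes plus
the atom-change classes observed in training (hydrogen/charge deltas — the
four bond classes alone cannot express atom edits, so the class list is
extended and stored in the vocabulary); a motif head over the vocabulary;
and an interface head conditioned on the predicted motif distribution.

The next input embedding combines the previous step's predicted
distributions through learned linear maps with the object embedding and
the current synthon embedding: after an edit,
$f_\pi(\hat\pi) + \sigma_e(e_{o_t}) + f_b(\hat r) + h^{t}_{syn}$; after
FinishEdit or a single-interface motif, $f_\pi(\hat\pi) +
\sigma_{att}(e_{m+a_t}) + h_{syn}$ with $a_t$ the attachment being
completed; after a multi-interface motif, $f_\pi(\hat\pi) + f_z(\hat z) +
f_q(\hat q) + h_{syn}$. The synthon embedding is recomputed after every
edit and frozen, in sanitized form (open valences refilled), at
FinishEdit — training and beam decoding use the same convention.
Attachment atoms created by motif attachment have no product entity
embedding; they use a learned "promoted attachment" vector instead.

## Training

Training is teacher-forced: the ground-truth prefix drives the graph
states and the conditioning entities, while predicted distributions are
fed to the next-input maps as the equations specify. The loss per step is
binary cross-entropy over the entity scores (the current step's true
entity is the positive; the alternative — labelling all reaction-center
entities positive at every edit step — is noted as an open choice) plus
cross-entropies for action, type, motif and interface, weighted 1:1 and
averaged per token.

Backpropagation is exact with one documented truncation: quantities that
are *recycled into the next step's input* — the predicted distributions,
the detached entity rows, and the synthon embeddings — are treated as
constants (stop-gradient). Every parameter keeps a primary gradient path
(heads, GRU, conditioning entities, readout, encoder); the truncation only
drops the secondary paths through the recycled inputs. The test suite
verifies the analytic gradients against central finite differences of
exactly this objective.

Optimization is full-batch Adam (defaults: learning rate 2e-3, global
gradient-norm clip 5), deterministic given the seed. For the overfit
protocol — the package's training oracle — training stops when every
training path is reproduced exactly *and* the mean loss falls below 0.002.
The margin matters: beam scores are raw log-likelihood sums (no length
normalization), so until the action probabilities at multi-center branch
points saturate, a shorter off-path hypothesis can outrank a longer true
path even when teacher-forced argmax accuracy is perfect.

## Decoding and evaluation

Beam search expands one token per hypothesis per step, scoring candidates
by the sum of the factored head log-probabilities: $\log \hat\pi(\text{Edit})
+ \log \hat s_i + \log \hat r(c)$ for edits, $\log \hat\pi(\text{Add}) +
\log \hat z + \log \hat q$ for motifs (interfaces pre-filtered by element
match with the attachment). Expansions that fail a chemistry check —
valence overflow, no-op edit, interface element mismatch — are pruned
rather than penalized, so every emitted SMILES is valid. The global top-k
by cumulative log-likelihood survive each step; a hypothesis finishes when
its attachment queue empties; the length cap is 30 tokens. Atom mapping is
not needed at inference; products are re-ordered canonically first so the
entity space matches the training convention.

Evaluation is Top-k accuracy over canonical, map-free SMILES: a record
counts as a hit at rank $k$ if its ground-truth reactant multiset
(components canonicalized individually, ordered largest-first) appears
among the $k$ best deduplicated predictions.

## The synthetic-reaction generator

Real benchmark data cannot ship with the package, so every stage is
exercised on synthetic atom-mapped reactions built *forward*: reactant
cores are drawn from hand-written fragment pools, joined across one or two
single-bond reaction centers to form the product, and completed with
leaving groups from a pool that includes hydrogen-only completions,
halides, a sulfonate ester (which the cutting rules split into a
two-interface motif plus a ring motif) and a biaryl ether (rule-2
material); an amine-quaternization template exercises charge-type atom
edits. Ground-truth paths therefore exist by construction, and the
generator doubles as the round-trip oracle for every module. Product atoms
are mapped in random order to emulate the benchmark's numbering shortcut.

Two generator policies are deliberate: products are deduplicated (two
reactions with the same product but different reactants would make the
teacher-forced target ambiguous and exact recovery impossible), and
heteroatom sites take hydrogen completions only, which keeps the chemistry
plausible. What the fixtures do *not* emulate: the scale and diversity of
patent reaction data, stereochemistry at the reaction center, aromatic
bond changes, bond formation in the retro direction, and multi-synthon
leaving groups — reactions outside the supported path grammar are detected
and skipped with a counted reason during preprocessing. Passing tests
therefore demonstrate correctness of the machinery, not benchmark-level
accuracy on real chemistry.

## Numerical and degenerate-input choices

* Tie-breaks are deterministic everywhere: equal edit scores resolve to
  the lowest entity index; reactant components order by size then
  radix-sorted SMILES; vocabulary ids are radix-sorted keys.
* An identity reaction yields the two-token path Start/FinishEdit; applying
  it returns the product unchanged.
* Hydrogen counts at edit sites are refilled by smallest-standard-valence
  rules at path completion, unless an atom edit pinned them explicitly;
  motif-contributed atoms keep their stored (reactant) hydrogen counts.
* Aromatic bonds are excluded from edit targets; reactions whose center
  involves aromaticity changes are skipped during preprocessing.
* Parsing demotes "aromatic" bonds outside rings (the biaryl link written
  without an explicit single-bond symbol) to single bonds.

## Problem sizes

The package's own experiments run at documented compact scales: 200
synthetic reactions for the round-trip check, 20 reactions / $D=64$ /
$L=2$ for the overfit protocol (about 170 epochs), beam width 5 for
decoding, and exhaustive-enumeration comparisons on search spaces of a few
hundred paths. `scripts/acceptance.R` reproduces all of them from scratch.

## Known limitations

* Bond *formation* between mapped atoms in the retro direction has no
  entity in the product index space and is not representable; such records
  are skipped (rare in single-step benchmark data).
* A leaving group bonded to two different synthon atoms (macrocyclic
  bridges) is not supported.
* Stereochemistry is parsed, preserved through canonicalization and
  compared in evaluation, but edits do not create stereocenters.
* The gradient truncation described above biases gradients relative to
  full backpropagation through time; empirically it does not prevent exact
  overfitting, but large-scale training behaviour may differ.
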