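---
title: "Tree-structured fragment SMILES: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-structured fragment SMILES: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tsmiles)
```

## The representation

A classical SMILES string is a depth-first walk of the molecular graph:
branches become nested parentheses and rings become paired digits, so a
generative sequence model must learn long-range pairing constraints to emit
valid strings. `tsmiles` replaces the atom-level depth-first walk with a
fragment-level breadth-first one:

1. **Fragmentation.** The molecule is cut into chemically valid fragments
   under one of four schemes (below). Each fragment is an ordinary SMILES
   string; attachment information is encoded per *code style*:
   shared real atoms (`tssa`), unlabelled dummy atoms `*` (`tsdy`), or
   ID-labelled dummies `[n*]` (`tsid`). `vanilla` keeps the whole molecule
   as one fragment, so classical SMILES is a special case of the notation.
2. **Acyclic molecular tree (AMT).** Fragments become nodes of the reduced
   graph; because every cut severs an acyclic bond (and junction clusters
   are joined through shared atoms), the reduced graph is a tree. It is
   rooted and the children of each node are ordered deterministically.
3. **Full binary tree (FBT).** The AMT is embedded in a binary tree in
   which every node has zero or two children. Convention: the *left* child
   of a node holds its next sibling, the *right* child its first child;
   missing positions are empty nodes.
4. **Serialisation.** A level-order traversal emits fragment SMILES for
   fragment nodes and `&` for empty nodes; `^` separates two adjacent
   fragment tokens; one trailing `&` sentinel is appended. For a tree with
   $F$ fragments the stream holds $2F + 1$ structural tokens plus the
   sentinel, so the `&` count always equals $F + 2$ — a property the test
   suite checks on every encoder output.

Decoding reverses each stage. The level-order queue rebuild consumes the
token stream: the first fragment token is the root and every dequeued
fragment takes the next two tokens as children. Surplus trailing `&` are
accepted silently. With `repair = TRUE` (meant for model-emitted strings)
truncated streams are padded with `&`, surplus interior tokens are dropped
and unparseable fragment tokens are demoted to empty nodes; every repair is
counted so that downstream validity statistics stay honest.

## Fragmentation schemes

* **`brics`** — the published BRICS retrosynthetic environments
  (16 SMARTS classes and their compatibility pairs), transcribed in
  `R/brics-rules.R` and matched with Open Babel SMARTS. Each molecular
  bond is cut at most once, never inside a ring. The implementation was
  checked against an independent toolkit's BRICS fragmenter on six
  reference drugs (frozen multisets in the test suite).
* **`mmpa`** — matched-molecular-pair cuts. An *eligible* bond is single,
  acyclic, between heavy atoms, with at least one carbon end that is not
  multiply bonded to a heteroatom (the SMARTS is a config string,
  `ts_config(mmpa_smarts = ...)`). The cut policy has two phases:
  (1) every eligible bond touching a ring atom is cut; (2) any remaining
  acyclic fragment larger than `mmpa_max_acyclic` (default 3) real heavy
  atoms is split recursively at its most size-balanced eligible bond,
  ties broken by atom index. Phase 2 is what reproduces the worked
  example below: a CF3 group attached to a ring loses exactly one
  fluorine (4 heavy atoms → 1 + 3), while a sulfonamide — with no
  carbon-ended eligible bond — stays intact. Applying *all* eligible cuts
  would shatter CF3 into four pieces and does not reproduce the published
  decomposition.
* **`scaffold`** — the Murcko scaffold (ring atoms plus linkers, obtained
  by iteratively pruning non-ring leaves) is separated from its side
  chains; ring–linker bonds inside the scaffold are cut as well. Acyclic
  molecules have no scaffold and are kept whole with a warning.
* **`junction`** — under the shared-atom style, clusters are the
  fundamental rings (merged when sharing `ring_merge_shared = 3` or more
  atoms) plus every non-ring bond, connected by a maximum spanning tree of
  the shared-atom-count cluster graph, as in the junction-tree literature.
  Atoms shared by many clusters are *not* promoted to singleton clusters;
  the record-guided assembler instead merges every child atom whose source
  atom is already placed, which reconstructs fused and spiro systems
  exactly. Under dummy styles the junction scheme cuts every single
  acyclic bond incident to a ring atom (the reduced graph of ring systems
  versus substituents) — the cluster notion itself has no dummy-atom
  equivalent.

## Reassembly

Assembly is greedy and root-outward, one neighbourhood at a time, in the
order the tree was generated; no global search is performed. At each join:

* `tsid` — the child's labelled dummy is fused with the open dummy
  carrying the same ID anywhere in the partial molecule. The search is
  global rather than parent-local on purpose: the published worked
  example's own breadth-first layout places one branch under a terminal
  node of another, and only ID matching decodes it. The result is unique,
  whatever the selector.
* `tsdy` — candidates are all pairings of an open parent-fragment dummy
  with a child dummy of compatible bond order; if the parent fragment has
  none left, the search widens to the whole partial molecule. Restored
  bond order is the order spelled on the dummy bond in the fragment
  itself (so the rare double-bond BRICS cut survives a round trip).
* `tssa` — candidates superpose one child atom onto one atom of the
  parent fragment (same element and formal charge, merged bond-order sum
  within the valence table), or one child bond onto a parent bond for
  fused-ring clusters. Aromaticity conflicts are left to the final
  sanitization rather than prefiltered.

The selector decides among candidates: `record` replays the decomposition
records (exact source reconstruction), `random` draws uniformly — the
training-free generator — and `scored` draws `n_candidates` complete random
assemblies and keeps the best under a user scorer (scoring whole molecules,
not per-join picks). Random assemblies that fail sanitization are redrawn
(bounded at `max_attempts`), then the records are used as a fallback, so
reconstruction of a molecule's own tree always returns a valid molecule.
Dummy-style joins conserve valence exactly (a dummy occupies precisely the
slot the restored bond needs), which is why validity is structural rather
than statistical. Every returned molecule must pass sanitization: the
package's valence tables (charge-adjusted allowed bond-order sums; Open
Babel itself accepts hypervalent SMILES such as the three-bond oxygen in
`CO=CC`) plus a successful canonical serialisation.

## Numerical and policy choices

* **Determinism.** Every molecule graph is rebuilt from its Open Babel
  canonical SMILES, so isomorphic inputs give byte-identical graphs and
  all tie-breaks on atom indices are input-order independent. The default
  tree root is the fragment containing the first canonical atom; child
  order is descending subtree heavy-atom count, ties by fragment SMILES.
  `enumerate_roots()` provides the root-enumeration augmentation
  (one serialisation per fragment chosen as root).
* **Stereochemistry** is stripped at parse time. Fragment cuts can
  invalidate stereocentres, and keeping a single stereo-free canonical
  surface makes equality, novelty and round-trip checks mutually
  consistent. This is a deliberate narrowing: round trips preserve the
  constitution, not stereo-isomerism.
* **Salts.** Multi-component inputs keep the largest covalent component
  with a warning.
* **Aromatic vs Kekulé.** Fragment SMILES default to the aromatic
  lower-case dialect; `ts_config(kekule = TRUE)` writes Kekulé spellings
  (as in the embedded worked-example codes). Corpus token statistics are
  computed on the Kekulé form when comparability with those codes
  matters, since aromatic carbons then tokenize as `C`.
* **Distribution metrics.** The descriptor score is
  $\mathrm{mean}_d\,e^{-KL_d(\text{train}\,\|\,\text{gen})}$ with 1-D
  histograms (Freedman–Diaconis bins on the training side, Laplace
  smoothing $10^{-10}$) for continuous descriptors and union-support
  count tables for discrete ones; identical sets give exactly 1.
  Property distances are empirical 1-Wasserstein integrals of ECDF
  differences. The default descriptor set is MW, logP, TPSA and molar
  refractivity (continuous; Open Babel) plus H-bond donors/acceptors,
  heavy-atom and ring counts (discrete); synthetic-accessibility and
  drug-likeness scores would need an external toolkit and can be plugged
  in through `ts_property_set(extra = ...)`. A neural-embedding
  distribution distance (FCD) requires trained network weights and is
  deliberately not computed; the report carries a slot for an externally
  computed value.

## What the synthetic fixtures do and do not show

`generate_fixture_molecules()` grows molecules by seeded random attachment
of benzene, pyridine, cyclohexane and cyclopentane rings, short carbon
chains and terminal O/N/S/F atoms under exact valence bookkeeping
(defaults: 8–24 heavy atoms, ring seed probability 0.6 — a drug-like size
range in which every fragmentation scheme is non-trivial). Every output
sanitizes, and nearly all carry at least one eligible matched-pair bond,
so fragmentation tests are never vacuous. The fixtures deliberately do
*not* emulate charged species, fused polycycles, stereo centres,
macrocycles or exotic heteroatoms; passing the suite therefore
demonstrates the algebraic guarantees of the codec (round-trip identity,
validity by construction, novelty ordering) on representative scaffolds,
not corpus-level statistics of any public compound library — those depend
on the library version and are out of scope. The validation sizes used
throughout (500 fixture molecules for corpus-level checks, 1000 composed
trees for decode validity, 500 random trees for codec inversions) were
chosen once as the package's study conditions.

## Known limitations

* The shared-atom (`tssa`) candidate enumeration merges one atom or one
  bond; clusters overlapping in three or more atoms (heavily fused cages)
  are only guaranteed to reconstruct under the record-guided selector.
* Kekulé export relies on Open Babel's kekulization; a few exotic
  aromatic systems may fall back to the aromatic dialect.
* Fragment tokens are SMILES only; alternative fragment notations would
  slot in at `parse_fragment_token()` / fragment serialisation but are
  not shipped.
* Goal-directed assembly is plain best-of-n sampling; tree search or
  chemically guided editing is out of scope.
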