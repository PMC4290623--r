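---
title: "Conserved binding environments from interaction profiles: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved binding environments from interaction profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homopharma)
```

## The problem and the model

Proteins that present similar binding environments tend to be inhibited by
topologically similar compounds; conversely a compound family tends to bind
proteins with conserved sub-pockets. This package identifies groups of
protein–ligand complexes — *Homopharma groups* — that share a conserved
binding environment, similar compound topology, and similar protein–compound
interaction patterns.

The pipeline takes a query complex, a set of candidate complexes with
residue correspondences (produced upstream by a structure search; searching
itself is out of scope here), the bound compounds, and a multiple sequence
alignment (MSA) of the candidate chains. It applies two reservation filters
and then clusters conservation-weighted interaction profiles:

1. rigid-body superposition onto the query (Kabsch) with an RMSD ≤ 3 Å
   reservation;
2. atom-pair compound topology similarity with a ≥ 0.6 reservation;
3. geometric typing of protein–ligand contacts into binary interaction
   profiles over MSA columns;
4. conservation weighting, pairwise Tanimoto-form scoring, and two-way
   average-linkage clustering cut at similarity 0.6.

With $N$ member complexes and $f_{ik}$ the number of complexes whose residue
at MSA column $i$ contacts the ligand with interaction type $k$, the
conservation weight is $W_{ik} = f_{ik}/N$. For two profiles $A$ and $B$
with weighted channels $a_i = A_i W_i$ and $b_i = B_i W_i$, the interaction
similarity is

$$
\mathrm{Sc}(A,B) \;=\; \frac{\sum_i a_i b_i}
{\sum_i a_i^2 + \sum_i b_i^2 - \sum_i a_i b_i},
$$

a Tanimoto form: for binary profiles and unit weights it equals the set
Jaccard index of the two interaction-channel sets (this reduction is
verified against an independent oracle on 1,000 random instances in the
test suite). Both all-zero weighted vectors give $\mathrm{Sc} = 0$ by
definition (the 0/0 guard). The index $i$ runs over all
(column, type, chain-part) channels; we read the per-position weight as the
typed weight $W_{ik}$, since contact types and main-/side-chain parts are
recorded separately. A `collapse_types` option sums the three types per
column first, for users who prefer the untyped reading.

## Interaction typing

Empirical docking energies are deliberately not used: the similarity score
consumes only interaction presence and type, so the package types contacts
with a transparent geometric scheme. For every (protein heavy atom, ligand
heavy atom) pair, at most one event is emitted by exclusive precedence:

| type | criterion | default cutoff |
|---|---|---|
| electrostatic | opposite formal charges | ≤ 4.0 Å |
| hydrogen bond | donor/acceptor complement | ≤ 3.5 Å |
| van der Waals | any heavy-atom pair | ≤ 4.5 Å |

Donors, acceptors and formal charges come from a per-residue table (Lys NZ
donor and positive, Asp/Glu carboxylate oxygens acceptors and negative,
backbone N donor except proline, backbone O acceptor, and so on) and, for
ligands, from element/connectivity heuristics (hydroxyl-like O
donor+acceptor, carboxylate O negative, quaternary N positive). There is no
angular term for hydrogen bonds: hydrogens are absent from most crystal
structures, so a distance-only criterion avoids fabricating hydrogen
positions; the cost is occasional over-calling of borderline H-bonds, which
binary profiles tolerate. All cutoffs are configurable via
`interaction_params()`.

Profiles are binary by default. Whether an interaction profile should carry
presence or energy-like magnitudes is genuinely open; binary profiles are
what the conservation weight $f_{ik}$ (a complex count) consumes directly,
and a `count` mode is provided for users who want event multiplicities.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `rmsd_cutoff` | 3.0 Å | pocket reservation after Kabsch superposition |
| `atom_set` | CA | atoms entering the RMSD (CA / backbone / all-heavy) |
| `compound_threshold` | 0.6 | atom-pair Tanimoto reservation |
| `cut_similarity` | 0.6 | dendrogram cut (distance 0.4) |
| `linkage` | average | UPGMA agglomeration |
| `mode` | binary | profile values |
| `report_threshold` | 0.5 | within-group weight for "conserved" channels |

Which atoms enter the RMSD is not fixed by the method; CA is the default
because correspondences from structure-alignment tools are residue-level and
CA traces are insensitive to side-chain rebuilding; `backbone` and
`all-heavy` are exposed. The clustering linkage and cut are likewise open
choices: average linkage matches the interpretation of "group members are
similar on average", and the 0.6 cut mirrors the interaction-similarity
decision threshold used in the evaluations, so one number controls both.
Ties in `stats::hclust` merges are resolved by its fixed internal order,
making results deterministic for identical inputs.

Column indexing is 1-based everywhere (natural in R), including reports.

## Atom-pair similarity and its conventions

The atom-pair descriptor types each heavy atom as (element, heavy-neighbour
count, π-electron count) and records one multiset entry per connected atom
pair, keyed by the two canonically ordered types and the bond-count shortest
path. π counts are read off kekulized bond orders (one per double bond, two
per triple); atoms on aromatic-flagged SDF bonds contribute one. Pairs
spanning disconnected fragments are omitted. Similarity is multiset
Tanimoto; `ap_similarity(..., method = "dice")` provides the
matches-over-total form of the original atom-pair formulation.

Published one-decimal similarity values for reference pairs (MTX–COP 0.7,
MTX–DTM 0.3, EST–DES 0.8, EST–RAL 0.2) are *not* reproduced by this
implementation, which measures 0.4 / 0.2 / 0.2 / 0.1 on structures
transcribed from the chemical component dictionary
(`inst/extdata/ccd/*.sdf`). We scanned the documented convention space —
atom typing with and without neighbour/π terms, multiset Tanimoto versus
Dice, set semantics, topological-distance caps — and no standard convention
reproduces all four values; the software originally used for those numbers
is unidentified and its normalization is not recoverable. The corresponding
acceptance test asserts the published values and is expected to fail; the
package reports its own measured values and documents the convention
precisely, which we consider the more reproducible position. The 0.6
reservation threshold is kept as specified; users comparing against other AP
implementations should recalibrate the threshold to their similarity's
scale.

## Superposition

`kabsch_superpose()` is the standard SVD solution with reflection
correction ($\det R = +1$). RMSDs below $10^{-9}$ Å are floored to zero so
exact copies report RMSD 0 despite floating-point noise. Collinear point
sets trigger a warning (the rotation about the line is arbitrary; the RMSD
is still optimal). The implementation is verified against an independent
quaternion (Horn) oracle to $10^{-6}$ Å on random point sets.

## What the synthetic fixtures emulate — and what they do not

`make_pocket_complex()` builds idealized pockets: residues sit on rings of
radius 12 Å (8 per ring, stacked every 8 Å), each planted residue carries a
minimal atom set sufficient for role typing (Gly N for main-chain H-bonds,
Ser OG for side-chain H-bonds, Lys NZ for electrostatics, Ala CB / Gly CA
for van der Waals), and ligand probes sit exactly at the planted distance
(2.9 Å H-bond, 3.8 Å electrostatic, 4.2 Å vdW). Two geometric facts shape
the design:

* H-bond and vdW probes are single-atom ligand fragments. Any covalent
  neighbour of a probe placed at H-bond range necessarily falls inside the
  4.5 Å vdW cutoff, so a bonded probe cannot produce "exactly the planted
  event". Electrostatic plants use a real three-atom carboxylate,
  anti-aligned so only the charged oxygen is in range.
* Coordinate jitter (`rmsd_perturbation`, default 0.1 Å) models positional
  noise for the superposition pathway, but planted pair distances are
  re-imposed after jittering: without this, jitter occasionally pushed a
  3.8 Å electrostatic plant past the 4.0 Å cutoff, retyping it as vdW and
  silently adding channel noise beyond the nominal flip rate.
* Electrostatic main-chain plants are refused: backbone atoms carry no
  formal charge.

`make_homopharma_scenario()` assigns pocket positions round-robin to groups
(disjoint channel sets), drops each planted channel independently with
probability `channel_flip_noise` (default 0.05), shares one compound-edit
family across all complexes (20-atom chain scaffold, sized so one or two
point edits stay above the 0.6 topology threshold — on an $n$-atom chain a
single substitution scales AP similarity by roughly $(n-2)/(n+2)$), and
emits the alignment by construction, gapped at deleted residues. Noise is
confined to the complex's own planted set: because group channel sets are
disjoint, injecting a foreign channel would carry the foreign group's full
conservation weight, and the effective noise would far exceed the nominal
rate. Under the defaults this yields within-group similarity near 0.9 and
between-group similarity near 0; recovery (adjusted Rand index against the
planted grouping) averages above 0.99 over 50 seeded scenarios at the 5%
noise level, and degrades below 0.5 at 50% noise.

These fixtures exercise the detection rules, not physics: geometry is not
relaxed, residues are chemically minimal, sequences are short and
near-identical, and ligand probes are not drug-like molecules. Passing tests
therefore demonstrate correctness of the filtering, typing, scoring,
clustering and evaluation machinery — not performance on real crystal
structures, where contact geometry, alternate conformations and alignment
quality add noise sources the fixtures do not model.

## Degenerate inputs and numerical choices

* Fewer than 2 complexes surviving the filters: a singleton result with a
  warning, no clustering.
* All-zero weighted profiles: similarity 0 (0/0 guard); their diagonal in
  the similarity matrix is 0, not 1.
* Ligands with fewer than 2 heavy atoms: a typed `empty_fingerprint`
  condition; such candidates score 0 in reservation.
* Alternate locations: highest occupancy wins, ties broken by altloc label.
* The unit-weight Jaccard reduction and the weight-scale invariance of Sc
  (multiplying all weights by $c > 0$ leaves Sc unchanged for binary
  profiles) are asserted to $10^{-12}$.

## Validation-set grouping rules

`build_groups()` implements the inventory rules: union-find over complexes
sharing a protein or a compound; dropping groups whose complex count is
below 50% of all protein × compound combinations (kept at exactly 50%);
merging groups whose protein- or compound-set overlap exceeds 50% of the
smaller set, most-overlapping pair first, to a fixpoint. Two notes: the
density filter is applied before merging, following the order the rules are
stated in; and a connected component on $p$ proteins and $c$ compounds has
at least $p + c - 1$ complexes, so density exactly 0.5 first becomes
reachable at 3 × 4 — the boundary tests use such spanning-tree inventories.
Since union-find components are disjoint by construction, the merge step
only acts when groups originate elsewhere; it is exposed for that use and
for boundary testing.

## Known limitations

* No angular or solvation terms in contact typing; no π-stacking, halogen
  bond, or water-mediated contact types.
* Compound similarity is 2D-topological only; no conformer or pharmacophore
  comparison, and no stereochemistry awareness.
* The MSA is consumed, not produced; `center_star_align()` exists to build
  fixtures and is not a substitute for a production aligner on divergent
  sequences.
* Whether full chains or only pocket segments should be aligned before
  profiling is left to the caller (a column-subset can be applied upstream);
  profiles cover all mapped columns.
* The "surface compound" elimination rule is a pocket-burial proxy (fewer
  than 5 distinct residues with a heavy atom within 4.5 Å); the underlying
  notion has no standard definition, and both parameters are configurable.

## Problem sizes used in the shipped checks

The test suite and acceptance script run, per invocation: 1,000 random
Jaccard-reduction instances; 100 + 100 random superposition point sets
(up to 20 atoms); 50 planted scenarios of 3 groups × 8 complexes on
15-residue pockets; and benchmark fixtures of a few hundred labelled pairs.
These sizes keep a full run in the low tens of seconds on one CPU while
holding the Monte-Carlo standard error of the recovery statistic well below
the margins asserted.
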