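---
title: "Comparing and clustering protein assemblies across independent experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and clustering protein assemblies across independent experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatclust)
```

## The problem

A crystal structure determines a lattice, not a biological assembly: the
deposited coordinates are compatible with many candidate oligomers, and the
annotations in the major resources (author-assigned, interface-energy based,
sequence-conservation based) disagree for a substantial fraction of entries.
A data-driven criterion is recurrence: if the same oligomeric arrangement is
observed in several *independent* experiments — different crystal forms,
cryo-EM reconstructions, NMR ensembles — of the same or homologous proteins,
that recurrence is evidence the arrangement is real rather than a packing
artifact. `quatclust` implements the machinery this criterion needs: detect
interfaces, reduce an assembly to the interface types that hold it together,
decide whether two assemblies from different experiments are "the same", and
aggregate that decision into clusters and evidence statistics.

## Interfaces and the Q score

Two chains form an interface when they have at least ten pairs of
representative points (C-beta, with C-alpha substituted for glycine and for
residues lacking a C-beta) within 12 Å and at least one heavy-atom contact
within 5 Å, or at least five heavy-atom contacts within 5 Å. Only heavy
atoms are considered; most X-ray entries lack hydrogens, and including them
where present would bias the counts.

Interface similarity is a Q score on contacting residue pairs. Each
interface is a set of residue-position pairs (the C-beta pairs within 12 Å);
positions are first mapped into a shared homologous coordinate — Pfam HMM
match-state columns when a domain-assignment table is available, alignment
columns of a global pairwise alignment otherwise, and the identity map
within a single entry. With mapped pair sets $P_1$, $P_2$ and
$C = P_1 \cap P_2$:

$$Q = \frac{\sum_{p \in C} w(p)}{|P_1| + |P_2| - |C|}$$

In the reference (`jaccard`) mode $w(p) = 1$, so $Q$ is the Jaccard index of
the two pair sets and $Q(A, A) = 1$ holds by construction. The `distance`
mode down-weights common pairs whose representative-point distances disagree,
$w(p) = \exp(-\Delta d_p^2 / 2\sigma^2)$ with $\sigma = 3$ Å by default; it
never exceeds the Jaccard value. The kernel form and $\sigma$ are package
choices — the criterion the pipeline depends on is the Jaccard mode. For
isologous (head-to-head) interfaces the orientation of the pair $(i, j)$ is
ambiguous, so both orientations are scored and the larger value kept.

## Unique connecting interfaces

Within one assembly, interfaces are clustered by single linkage at
$Q \ge 0.75$ (identity position map — same entry, same numbering). Each
cluster is represented by its smallest interface id; representatives are
ordered by descending interface size (the C-beta pair count serves as the
buried-area proxy and sort key; ties break toward the smaller id). The
*unique connecting interfaces* are accumulated by walking the clusters in
that order: add the representative, then sweep the cluster's member
interfaces, seeding the connected-chain set with the first interface and
afterwards consuming an interface only when exactly one endpoint is already
connected; stop once every chain is covered. One detail is deliberate: the
sweep repeats over unconsumed members until a fixed point before moving to
the next cluster, because a single pass in an unlucky member order can
strand a chain even though the cluster connects everything. The repeat
preserves the intent (all chains connected) and guarantees termination.

On ideal fixtures this reduction gives the textbook answers: a $C_n$ ring
has exactly one connecting interface (the one heterologous contact repeated
around the cycle), an ideal $D_2$ tetramer exactly two (the dimer interface
plus the inter-dimer one), larger $D_n$ at least two, one of them
heterologous.

## Binary similarity and clustering

Assemblies are only compared within a cell: same assembly Pfam architecture
(copy counts included) and same symmetry label — a $C_3$ trimer is never
compared to a $C_4$ tetramer. Within a cell, $S_{12} = 1$ iff every
connecting interface of assembly 1 (largest first) matches some unique
interface of assembly 2 at $Q \ge q_\text{match}$, and
$S = S_{12} \times S_{21}$. The cross-entry match threshold
$q_\text{match} = 0.5$ is a package default: cross-homolog Q values around
0.68 are confidently similar interfaces yet would fail the within-assembly
0.75 cut, so the cross-entry threshold must sit below it; 0.5 is exposed in
the configuration. Single-linkage clustering over $S = 1$ yields the
assembly clusters; both the relation and the clustering are invariant to
input order and to rigid-body motion of whole assemblies, which the test
suite checks as metamorphic properties.

## Symmetry and pseudo-symmetry

The point-group detector works from candidate rotations: superpose every
chain that is interchangeable with a reference chain (the longest; ties by
chain id) onto that reference about the assembly centroid (orthogonal
Procrustes, no translation term), keep rotations with RMSD ≤ 3 Å, and
validate each candidate by requiring it to map *every* chain onto some chain
of the same group within the same tolerance. The validated set is classified
by rotation angles and axes: all non-identity axes colinear with angles at
multiples of $360/n$ (within 8°) gives $C_n$; an order-$n$ principal axis
plus $n$ perpendicular 2-folds (within 10°) gives $D_n$; validated orders of
12, 24 or 60 that fit neither pattern are labelled polyhedral; otherwise
`C1` or `unknown`.

Two grouping modes matter for heteromers. In `strict_entity` mode only
chains of one sequence entity are interchangeable, so an A3B3 hexamer of two
homologous proteins can show at most $C_3$. In `pseudo_by_arch` mode chains
sharing a chain Pfam architecture are interchangeable, and the same hexamer
is recognized as (pseudo-)$D_3$ — the label used for the clustering gate in
same-architecture hetero cells, so that A3B3 and A6 assemblies of one
architecture land in one cell; the strict label is retained in the output.
The tolerances (3 Å, 8°, 10°) are package decisions exposed in the
configuration; the synthetic fixtures are exact, so tests do not depend on
them. Helical/filamentous arrangements are out of scope: open filaments fail
rotation closure and return `unknown` (or `C1`).

## Crystal forms

An entry group (same entry Pfam architecture) is partitioned into crystal
forms: two X-ray entries share a form when their space groups are identical
and each of the six cell parameters agrees within 5%, read as a symmetric
relative difference $|p_A - p_B| / \max(p_A, p_B) \le 0.05$ and applied to
angles in degrees as printed. The pairwise relation is not transitive, so
the partition is its single-linkage closure — consistent with how single
linkage is used everywhere else in the pipeline. Every cryo-EM or NMR entry
counts as its own crystal form (one independent experiment). The evidence
statistic for a cluster, `R_CF_UNPclus`, is the number of crystal forms in
the cluster containing a given protein divided by that protein's crystal
forms in the whole corpus, summed over the cluster's proteins with defined
keys for the cluster-level ratio; text output rounds to two decimals
(`0.71` for 5 of 7), JSON keeps full precision. Entries without entity keys
still count toward a cluster's #CFs but are left out of the ratio.

## Architecture strings

Chain architectures list Pfam domains N-to-C, each in parentheses, joined by
underscores (`(Cyclin_N)_(Cyclin_C)`). A domain split by an inserted domain
is rendered with its match-state spans (`(IMPDH[1-82])_(CBS)_(CBS)_(IMPDH[83-345])`);
a repeated domain whose copies span the same columns is a tandem repeat and
keeps the plain form. Entry architectures concatenate the unique chain
architectures in lexicographic order — a canonical order is required because
the string is a grouping key. Assembly architectures add copy counts
(`(Pkinase)2`). Chains with no Pfam hit get `(NA)` and still participate in
grouping. Assignments are consumed as a table (the thresholds of the
upstream HMM pipeline — HMMER 1e-5, HHsearch 1e-4, FATCAT 1e-3 — document
its expected provenance; the package does not run those tools). Without a
table, positions are mapped through global pairwise alignment (match 1,
mismatch −1, gap open 10, extend 0.5) onto the longest chain of the
architecture group.

## What the synthetic fixtures emulate

The generator builds exact oligomers from a pseudo-protein chain: a compact
ball of residues on a Fibonacci sphere (radius 4 Å) plus a six-residue arm
aimed at the next subunit, with CA, CB and one side-chain proxy atom per
residue. Rings place $n$ copies at exact $360/n$ rotations; dihedral
assemblies stack two rings under an exact perpendicular 2-fold (half-gap
6.6 Å, neighbour distance 17 Å — sized so that arm-to-ball contacts satisfy
the interface criterion while non-neighbours stay beyond it, which the
generator asserts at build time). The two-faces scenario builds two D2
tetramers on one shared C2 dimer, stacked through opposite faces of the
ball, so the tetramers share the dimer interface and nothing else — the
pattern seen in enzyme families where distinct tetramers contain one
conserved dimer. The toy corpus writes these assemblies as mmCIF files with
synthetic cells and space groups realizing a chosen crystal-form structure,
plus identity-map domain assignments and entity keys, and returns the
expected cluster manifest.

What the fixtures do *not* emulate: real side-chain packing and buried
surface areas (the area proxy is a pair count), conformational variability
between homologs (fixture homologs differ in sequence but share exact
geometry, so cross-entry Q scores are 1 rather than ~0.7), missing residues,
altloc/occupancy noise, and lattice contacts competing with biological
interfaces. Passing tests therefore demonstrate the algorithms — criteria,
reductions, group detection, clustering, statistics — not robustness to
experimental noise; the tolerance parameters exist for real data and are
untouched by the fixtures.

## Numerical choices and degenerate inputs

* Ties in the area ordering of interface representatives break toward the
  smaller interface id; cluster ids and member order are fully deterministic
  so identical inputs give byte-identical reports.
* Chains with fewer than 3 resolved residues are dropped at read time (they
  cannot support superposition); symmetry detection refuses chains with
  fewer than 3 aligned positions.
* Altlocs keep the highest-occupancy conformer (ties alphabetically); only
  model 1 of multi-model NMR files is read (configurable), since the
  ensemble members are not independent experiments.
* Rotation decomposition near 180° avoids the vanishing skew part by taking
  the +1 eigenvector.
* A Q score between two interfaces with no mapped positions on either side
  is undefined and raised as an error rather than silently scored 0; an
  entity with zero corpus crystal forms is a data inconsistency, not a 0/0.
* Assemblies whose chain/interface graph is disconnected are excluded from
  clustering and logged with a reason.

## Problem sizes

The test suite and the acceptance script run on fixtures of 30-residue
chains and assemblies of up to 16 chains, toy corpora of 6–12 assembly
files, and 100 randomized crystal-form tables; the whole suite completes in
under two minutes on one CPU. These sizes were chosen because every
algorithmic branch (ring closure, dihedral stacking, pseudo-symmetry,
two-faces incompatibility, CF closure) is already exercised at them; the
algorithms scale to realistic corpora but the package ships no downloaded
data.

## Known limitations

* Candidate assemblies are consumed as input files (or generated); the
  package does not enumerate lattice assemblies from crystallographic
  symmetry, and it does not compute solvent-accessible surface areas — the
  interface sort key is the contact-pair count unless a caller supplies
  areas.
* Helical symmetry is not detected; polyhedral groups are recognized by
  order only, not subclassified.
* The sequence-identity fallback for entities uses global alignment identity
  at 0.95, which can split constructs with long tags; supplying explicit
  entity keys avoids this.
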