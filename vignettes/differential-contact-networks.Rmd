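---
title: "Differential analysis of protein contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential analysis of protein contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcndiff)
```

## The model

A protein contact network (PCN) is a coarse-grained view of a folded
chain: one node per residue, located at its C-alpha atom, and an
undirected edge between residues $i$ and $j$ whenever

$$ A_{ij} = \begin{cases} 1 & D_{ij} < r_c,\; i \neq j \\ 0 & \text{otherwise} \end{cases} $$

where $D_{ij}$ is the C-alpha–C-alpha distance and $r_c$ the contact
cutoff. The default cutoff is 7.0 Å (0.7 nm), the widely used estimate
of the first interaction shell for C-alpha networks; the inequality is
strict, so a pair at exactly 7.0 Å is *not* a contact. Sequence
neighbours are kept like any other pair — no separation exclusion is
applied, so a helix contributes its characteristic $i \to i+1 \ldots
i+4$ short-range edge pattern.

The package's central question is differential: given a reference
structure and a series of point mutants of essentially identical fold
(cross-structure RMSD well under 1 Å), which contacts appear, which
disappear, and what do those changes do to each residue's position in
the network? A new contact means two residues moved closer than the
cutoff; a lost one means they moved apart. Even when global descriptors
barely move, the set of made/lost contacts, their location (loops,
termini, active site, secondary-structure elements) and the induced
shifts in centrality can be highly structured — this is the signal the
pipeline extracts.

## Pipeline stages and their parameters

**Structure input** (`parse_structure`). Standard fixed-column PDB via
the bio3d parser; first protein chain unless one is named; HETATM and
waters dropped; one C-alpha per residue with alternate locations
resolved by highest occupancy (ties to altLoc "A"); first MODEL only.
Secondary structure comes from the HELIX/SHEET header records, or from
an external two-column file (residue number, H/E/C) when a different
assignment (e.g. DSSP) is preferred; unannotated residues are loops.
Role annotations (`annotation_config`) attach catalytic, active-site
and mutated flags by author residue number, and every configured number
must resolve — a typo'd configuration is rejected rather than silently
ignored.

**Contact classification** (`classify_contacts`). Each contact gets:

| flag | rule | default knob |
|---|---|---|
| `range_class` | long iff sequence separation > threshold | 12 positions |
| `involves_loop` | either endpoint in a loop | — |
| `involves_terminus` | either endpoint within the terminal window of a chain end | 4 positions |
| `near_active_site` | endpoint annotated active-site, or within a radius of a catalytic C-alpha | 7.0 Å |
| `connects_regular_ss` | both endpoints in regular secondary structure, in *different* elements | — |

"Long-range" has no universal definition; the threshold of 12 is
chosen so that the full intra-helical pattern (separations up to 4) and
short hairpin turns are unambiguously short-range, while contacts
between residues more than one secondary-structure element apart count
as long-range. It is a configuration knob, and analyses that need a
different convention (e.g. to match a published count) should set it
explicitly.

**Metrics** (`metric_table` and friends). Degree, Watts–Strogatz local
clustering, betweenness (Brandes' algorithm on the unweighted graph,
unnormalized by default since the interesting quantity here is the
*difference* between structures), closeness (reachable count over
summed hop distance, computed per component so synthetic or fragmented
inputs stay well-defined) and all-pairs BFS hop distances. These are
implemented directly on the adjacency matrix; the test suite checks
every one of them against an independent graph library and brute-force
oracles on hundreds of random graphs. Outlier residues are selected by
z-score standardised within the structure's own residue population
(population standard deviation, the within-network standardisation
convention), with strict thresholds — by default 2.5 for betweenness
and 2.0 for clustering. A constant metric yields an empty selection
with a warning, not an error.

**Communities** (`fast_greedy`). Clauset–Newman–Moore greedy
agglomeration of modularity

$$ Q = \sum_c \left( e_{cc} - a_c^2 \right) $$

merging, at each step, the connected pair of communities with the
largest $\Delta Q$ and returning the partition at the maximum of $Q$
along the merge sequence. Greedy merge order is not unique when gains
tie; ties are broken on the lexicographically smallest (min id, max id)
pair of community ids, which makes runs bit-reproducible. Unconnected
communities are never merged (their $\Delta Q$ is always negative), so
communities never span disconnected components. Partition comparisons
(`compare_partitions`) match communities greedily by maximum residue
overlap — adequate and deterministic for the handful of communities a
single-domain PCN has — and report reassignments, splits and merges; a
split/merge target must overlap by at least 3 residues, filtering
single-residue flicker.

**Superposition** (`kabsch`, `rmsd_matrix`, `residuewise_rmsd`).
Least-squares rigid superposition via SVD of the cross-covariance
matrix with the standard reflection guard (flip the smallest singular
direction when the determinant is negative), over all matched C-alpha
pairs with unit weights. Degenerate inputs (fewer than 3 points, or
collinear sets, detected at a relative singular-value tolerance of
1e-8) are errors. The residue-wise RMSD of an ensemble superposes every
structure onto a reference and reports, per residue, the RMS deviation
of its C-alpha about the ensemble-mean position (reference included) —
the usual picture of where a set of near-identical crystal structures
actually differs. Note that a published cross-structure RMSD computed
by a fragment-based alignment service may differ in the third decimal
from the all-C-alpha least-squares value; this package deliberately
uses the reproducible least-squares convention.

**Differential reports** (`diff_contacts`, `union_contacts`). Contact
identity across structures is the author residue-number pair, so
made/lost sets survive renumber-free crystallographic series.
Comparison is restricted to the residues present in both structures;
contacts touching unmatched residues are listed separately, never
counted as changes (missing density must not masquerade as a contact
change). Networks built at different cutoffs refuse to compare. Made
contacts are classified on the mutant structure, lost contacts on the
reference — each on the structure where the contact exists. The union
across a mutant series dedupes by residue pair; a deduplicated
contact's flags are taken from the first mutant in which it occurs
(flags depending only on the pair, like the range class, are identical
everywhere; secondary-structure-dependent flags rarely differ across
near-identical structures, and the per-mutant reports retain the
per-structure values).

## The synthetic generator

Downstream stages need inputs whose correct answer is known exactly.
`make_synthetic_structure` lays helices (canonical geometry: 1.5 Å
rise, 100° twist, 2.3 Å radius — chosen so contacts are exactly the
$i\pm1\ldots i\pm4$ pattern at 7 Å), strands and connecting coils as an
antiparallel meander, packing consecutive regular segments about 4 Å
plus their packing radii apart so the fold has genuine long-range
contacts. Seeded Gaussian jitter (default 0.2 Å for the lipase-sized
fold, roughly the coordinate spread between closely related crystal
structures) makes ensembles.

`make_mutant` applies ground-truth *contact edits*: an injection moves
an endpoint of a chosen pair along the pair axis until just inside the
cutoff (margin 0.3 Å), a removal to just outside. Candidate placements
move one endpoint, the other, or both half-way; the first placement
that flips exactly the requested pair — verified by brute-force
comparison of the full before/after contact maps — is kept, and if
none exists the edit set is rejected outright (never silently partially
applied). Direct endpoint moves with post-hoc verification were chosen
over bending a whole local neighbourhood: side-effect-free analytic
placement is intractable in general, and the audit makes the simpler
move both honest and sufficient. `sample_edit_set` draws seeded,
jointly feasible edit sets with disjoint residues, which is what the
recovery tests and the end-to-end validation use.

What the generator does *not* emulate: side chains, realistic backbone
dihedrals, chain-break-free loop closure (coil bridges can compress
consecutive spacing below 3.8 Å), or the correlated, physically
relaxed displacements real mutations cause. Passing the recovery tests
therefore demonstrates that the bookkeeping — contact sets,
classification, unions, deltas — is exact, not that the geometry
generator is a protein model. Conclusions about real mutant series
rest on the PCN definition itself, which is applied to real
coordinates identically.

## Problem sizes used in validation

The standard synthetic study is a 181-residue alpha/beta fold (six
strands, five helices, nine-residue loops — `lipase_like_spec()`, the
size of a small bacterial lipase chain) with six mutants carrying 3 to
13 seeded contact edits, mirroring a directed-evolution series of
cumulative point mutations. Property batteries run on 200 random
graphs of 5–50 nodes (metrics vs. independent oracles), exhaustive
partition enumeration up to 8 nodes (modularity optimum), 100 seeded
mutants (exact recovery), and 1000 random rotations (superposition
optimality).

## Known limitations

- Residue correspondence is by author numbering only; homologs that
  need sequence alignment are out of scope.
- Contacts are purely geometric C-alpha proximities: no energies, no
  interaction typing (hydrogen bond, salt bridge, stacking), no
  side-chain awareness.
- Greedy modularity is resolution-limited and tie-break-sensitive;
  community *counts* are robust in practice, exact memberships near
  merge boundaries are not, which is why partition comparison reports
  overlaps rather than asserting label equality.
- The fragment-based structure-alignment conventions of web services
  are not reproduced; cross-structure RMSD values here are plain
  least-squares over all matched C-alpha pairs.
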