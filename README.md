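# pcndiff

Differential analysis of protein contact networks (PCNs) in R.

## The problem

Point mutations that raise a protein's thermostability often leave its
three-dimensional structure essentially unchanged — crystal structures
of a directed-evolution series can superpose to well under 1 Å RMSD —
yet the stability gain is real. At that level, global descriptors
(overall RMSD, average network statistics) are uninformative. The
signal lives in *which residue–residue contacts appear and disappear*,
where those changes sit (loops, termini, around the active site,
between secondary-structure elements), and how they reorganise the
residue network's communication structure.

`pcndiff` is for structural bioinformaticians comparing a reference
crystal structure against a series of near-isomorphous mutants. It
builds coarse-grained C-alpha contact networks, computes residue-level
network metrics and modularity communities from scratch, superposes the
series, and produces classified reports of the contacts made and lost
by each mutant — the analysis style used to dissect thermostable
mutant series such as *Bacillus subtilis* Lipase A (helpers for that
seven-structure series are included).

## The model

One node per residue at its C-alpha; an edge whenever

    A_ij = 1  iff  D_ij < r_c   (i ≠ j, strict inequality)

with cutoff `r_c = 7.0 Å` (0.7 nm) by default. On top of this graph the
package computes degree `k_i`, Watts–Strogatz clustering
`C_i = 2e_i / k_i(k_i−1)`, Brandes betweenness, per-component
closeness, BFS shortest paths, z-score outlier selection (population
sd, strict threshold), and Clauset–Newman–Moore fast-greedy modularity
`Q = Σ_c (e_cc − a_c²)` with deterministic tie-breaking. Structure
superposition is least-squares (Kabsch via SVD, reflection-guarded).
Differential reports identify contacts by author residue-number pair,
compare only the matched residue intersection, and classify every
change (long/short range, loop, terminus, active-site proximity,
connecting regular secondary structures).

A synthetic-backbone module generates helix/strand/coil folds with
seeded jitter and "mutants" carrying exact, brute-force-verified
ground-truth contact edits, so every downstream stage is testable
without downloading anything.

## Worked example

```r
library(pcndiff)

ref <- make_synthetic_structure(lipase_like_spec(seed = 1), id = "REF")
ref_net <- build_pcn(ref, cutoff = 7.0)
ref_net
#> pcn 'REF': 181 nodes, 1176 contacts at 7.00 A cutoff

mut <- make_mutant(ref, sample_edit_set(ref, n_inject = 3, n_remove = 2,
                                        seed = 9), id = "MUT")
rep <- diff_contacts(ref_net, build_pcn(mut))
rep
#> diff_report MUT vs REF (cutoff 7.00 A): 3 made, 2 lost

rep$made[, c("resno_i", "resno_j", "separation", "range_class", "involves_loop")]
#>   resno_i resno_j separation range_class involves_loop
#> 1      20      37         17        long         FALSE
#> 2      92     101          9       short          TRUE
#> 3     132     141          9       short          TRUE

head(bc_gain_ranking(rep, top_k = 5), 3)
#>   resno d_betweenness
#> 1   132      691.8646
#> 2   106      448.9828
#> 3   141      445.3084

fast_greedy(ref_net)
#> community_partition 'REF': 6 communities, Q = 0.7240

superpose_structures(ref, mut)$rmsd
#> [1] 0.09564634
```

The made contacts are exactly the three injected pairs (the ground
truth is stored in `attr(mut, "contact_edits")`); the new 20–37
contact is long-range (separation 17 > 12), and the two residues whose
betweenness rises most (132, 141) are endpoints of a new contact — new
edges create new shortest paths through their endpoints. The 0.096 Å
C-alpha RMSD shows how small the coordinate perturbation producing
these network changes is.

`run_pipeline(ref, list(mut1, mut2, ...), run_config(), out_dir = "out")`
runs every stage (networks, metrics with z-score selections,
communities, RMSD matrix, residue-wise RMSD, per-mutant diff reports,
the cross-mutant union, ring-graph layouts) and writes a deterministic
TSV/JSON bundle. For the Lipase A thermostability series, download PDB
entries 1I6W, 1T4M, 1T2N, 3D2A, 3D2B, 3D2C, 3QMM into a directory and
call `reproduce_lipase("that/dir")`; its `headline` element collects
the node count, per-mutant and union made/lost counts with loop and
range breakdowns, the community counts and the maximum cross-structure
RMSD.

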