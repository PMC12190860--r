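# allonet

Ensemble-based residue interaction networks and allosteric hotspot
profiling for protein complexes.

## The problem

Allosteric communication in a protein complex — how binding or mutation
at one site reshapes dynamics at a distant one — is invisible to a single
static structure. Given a *conformational ensemble* (MD trajectory frames
as a multi-model PDB, or any frames × atoms × 3 coordinate table),
allonet quantifies which residues carry that communication and which
mutations would disrupt it. It is aimed at structural bioinformaticians
who have ensembles of a two-chain complex (e.g. a GTPase bound to an
engineered binder) and want reproducible, testable network statistics
rather than one-off scripts.

## The methods at its core

- **Dynamic cross-correlation matrix** over Cα displacements from the
  ensemble mean: `C_ij = ⟨Δr_i·Δr_j⟩ / (⟨Δr_i²⟩⟨Δr_j²⟩)^{1/2}`, plus the
  mutual-information **generalized correlation**
  `r_ij = sqrt(1 − exp(−2 I_ij/3)) ∈ [0, 1]`.
- **Ensemble-averaged mutational scanning**: every position × 20
  substitutions scored per frame by a pluggable scorer (a documented
  contact potential is built in), averaged over equilibrium samples;
  positive ΔΔG = destabilizing. Interface residues are detected at 5 Å
  heavy-atom cutoff with frame-majority occupancy.
- **Dynamically weighted residue graph**: edges where contact occupancy
  ≥ τ, coupling `g` from correlations (optionally mixed with
  coevolutionary mutual information), communication distance
  `d = −ln g`, backbone-connected.
- **Shortest-path betweenness centrality (SPC)**, normalized per node by
  the `(N−1)(N−2)/2` pairs of its component, and **mutational network
  perturbation**: remove or reweight each node, record the change of the
  characteristic path length (ASPL) per substitution, aggregate
  `ΔL_i = ⟨|ΔL_i^j|²⟩`, and standardize to `Z_i = (ΔL_i − ⟨ΔL⟩)/σ`.
  High-Z residues are allosteric hotspot candidates.

A synthetic-data module generates elastic-network ensembles, two-chain
complexes with planted interfaces, bottleneck graphs and coupled
alignments with *analytic* ground truth, so every stage is testable
without external data.

## Worked example

```r
library(allonet)

# a 24+14-residue synthetic complex, 5 planted interface residues
res <- make_toy_complex(n_a = 24, n_b = 14, n_interface_contacts = 5,
                        seed = 3, n_frames = 500)
res$ensemble
#> ConformationalEnsemble: 500 frames, 76 atoms, 38 residues, 2 chain(s)

identify_interface_residues(res$ensemble, "A", "B",
                            cutoff = 5, min_occupancy = 0.5)
#> [1] "A:10" "A:11" "A:12" "A:13" "A:14"
```

The detected interface is exactly the planted one. Build the weighted
residue graph and profile it:

```r
occ   <- compute_contact_occupancy(res$ensemble, cutoff = 5)
gcorr <- compute_generalized_correlation(res$ensemble)
graph <- build_residue_graph(occ, gcorr, tau = 0.5,
                             reference = res$ensemble$reference)
graph
#> ResidueGraph: 38 nodes, 46 edges

compute_spc(graph)
#> CentralityProfile: 38 residues, max SPC  0.4054

prof <- profile_perturbations(graph, mode = "remove", observable = "aspl")
prof
#> PerturbationProfile (remove/aspl): 38 residues, top Z at A:14 (2.85)
head(rank_hotspots(prof, z_min = 1))
#> [1] "A:14" "A:15" "A:16" "A:17" "A:18" "A:10"
```

The top-Z residues sit at and just downstream of the interface block —
the only region carrying inter-chain communication in this toy complex,
so removing those nodes stretches the network's characteristic path
length the most. Mutational scanning over the interface:

```r
scan <- scan_mutations(res$ensemble,
                       builtin_contact_scorer(burial_weight = 0.5),
                       positions = identify_interface_residues(
                         res$ensemble, "A", "B"),
                       n_samples = 500)
round(scan$ddg[1:3, c("A", "D", "F", "K", "L", "W")], 3)
#>           A     D      F      K      L      W
#> A:10  0.000 0.007 -0.001  0.008 -0.003  0.004
#> A:11  0.170 0.000  0.202 -0.013  0.234  0.083
#> A:12 -0.012 0.007 -0.016  0.008 -0.020 -0.003
```

Each entry is the ensemble-averaged ΔΔG (kcal/mol) of one substitution;
the wild-type column is exactly 0 (A:10 is an alanine, A:11 an
aspartate), and positive entries weaken binding. `export_heatmap()`
writes the 20 × positions CSV and a diverging heatmap image;
`run_pipeline(pipeline_config(...))` chains every stage with a
deterministic manifest, and `render_profiles()` draws the RMSF, SPC, Z
and heatmap figures from the CSVs.

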