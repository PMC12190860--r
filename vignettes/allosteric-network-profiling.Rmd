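---
title: "Ensemble-based residue interaction networks and allosteric hotspot profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-based residue interaction networks and allosteric hotspot profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The model

allonet analyses conformational ensembles of protein complexes — multi-model
PDB files or coordinate tables standing in for MD trajectory frames — to
locate residues that control long-range (allosteric) communication. The
pipeline has four statistical layers.

**Dynamics.** After least-squares superposition of every frame onto the
reference structure, per-residue fluctuations are summarized by the RMSF
and by the dynamic cross-correlation matrix (DCCM) over Cα displacements
from the ensemble-mean position,

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
  {\left(\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle\right)^{1/2}},$$

with $C_{ij} > 0$ marking correlated and $C_{ij} < 0$ anti-correlated
motion. The displacements are taken about the ensemble mean, not the
reference structure: that is the standard definition and makes
$C_{ii} = 1$ exact. A nonlinear counterpart, the generalized correlation
$r_{ij} \in [0, 1]$, is derived from the Gaussian mutual information of
the 6×6 joint Cα covariance of a residue pair,
$I_{ij} = \tfrac12 \ln\left(\det\Sigma_i \det\Sigma_j / \det\Sigma_{ij}\right)$
and $r_{ij} = \sqrt{1 - e^{-2I_{ij}/3}}$. The linear-Gaussian closed form
was chosen deliberately: it is exactly testable against hand-computed
covariances (a cross-block correlation $\rho$ gives $r = |\rho|$
analytically) and it guarantees $r_{ij} \ge |C_{ij}|$ on Gaussian
ensembles, which the test suite checks.

**Mutational scanning.** Binding free-energy changes
$\Delta\Delta G_{\mathrm{bind}} = \Delta G^{\mathrm{mut}}_{\mathrm{bind}} -
\Delta G^{\mathrm{wt}}_{\mathrm{bind}}$ of all 20 substitutions at scanned
positions are evaluated per frame by a pluggable `SubstitutionScorer` and
averaged over equilibrium samples (default 1000 frames, stride-selected),
rather than scored on a single mean structure. Positive values are
destabilizing. The built-in scorer is a simple, fully documented contact
potential — the sum over cross-chain contact partners of tabulated pair
energies, plus an optional hydrophobic-burial term using a contact-count
burial proxy instead of a true SASA — so the whole ensemble-averaging
machinery is self-contained and reproducible. Structure-trained statistical
potentials can be plugged in through the same interface. Interface
residues are detected as those with heavy atoms within 5 Å of the partner
chains in at least half of the frames; the 5 Å cutoff is the conventional
contact criterion, and the frame-majority occupancy rule makes the
definition ensemble-aware and deterministic.

**Residue interaction network.** Residues are nodes; a pair is joined when
its contact occupancy (fraction of frames with side-chain heavy atoms
within the cutoff) reaches the threshold $\tau$ (default 0.5). Glycine
contributes its Cα in side-chain mode. The edge coupling
$g \in (0, 1]$ is the generalized correlation (or $|C_{ij}|$ for a signed
DCCM), optionally mixed with min–max-normalized coevolutionary mutual
information from an alignment: $g = (1-\lambda) g_{\mathrm{dyn}} +
\lambda g_{\mathrm{coev}}$. Since no standard definition exists for the
coevolutionary combination, $\lambda$ defaults to 0 (dynamics only) and
the MI mixing is an explicit, documented option. The communication
distance is $d = -\ln g$, the usual information-flow convention: strongly
coupled pairs are close, the transform is exactly invertible for testing,
and couplings are clamped to $[0.01,\ 1 - 10^{-9}]$ so a single edge can
contribute at most $\ln 100$ of distance — decorrelated contacts must not
become infinitely long. Consecutive residues of a chain are always
connected (backbone augmentation): side-chain contact edges alone can
disconnect loop regions, while communication physically propagates along
the backbone, and the centrality normalization presumes meaningful path
structure.

**Centrality and perturbation profiling.** The shortest-path betweenness
centrality of node $i$ sums, over node pairs $(j, k)$, the fraction
$g_{jk}(i)/g_{jk}$ of minimal-distance paths through $i$, normalized by
the $(N-1)(N-2)/2$ node pairs excluding $i$ within its connected
component, so a star center scores exactly 1. (The source literature
prints the normalization both as $(N-1)(N-2)$ and, in prose, as
$(N-1)(N-2)/2$ pairs; the pair count is the standard convention for
undirected graphs and is the one that attains 1 at a star center, so it
is used here.) Mutational network profiling perturbs each node — either
removing it, the classical centrality probe, or reweighting its incident
couplings by a substitution similarity $s(\mathrm{wt}, \mathrm{mut}) \in
[0, 1]$ derived from BLOSUM62 normalized odds — and records the change of
a global observable for each of the 19 substitutions:
$\Delta L_i = \langle |\Delta L_i^{(j)}|^2 \rangle_j$ (a literal mean of
squared changes; RMS and mean-absolute variants are offered because the
squared-magnitude notation may well intend an RMS, but the printed form
wins by default). The per-node Z-score
$Z_i = (\Delta L_i - \overline{\Delta L})/\sigma$ uses the *population*
standard deviation: standardizing over a fixed finite node set is a
normalization, not an inference, so $\mathrm{mean}(Z) = 0$ and
$\mathrm{popsd}(Z) = 1$ hold to $10^{-10}$ whenever $\sigma > 0$ (and
$Z \equiv 0$ otherwise). Residues with $Z \ge 1$ are reported as
allosteric hotspot candidates.

Two observables are implemented because the source describes both: the
average shortest-path length (ASPL, characteristic path length) over
reachable pairs, and the per-node SPC profile. ASPL under node removal is
the default for Z profiles; SPC remains available. When a removal
disconnects a component the ASPL is taken over the remaining reachable
pairs (never infinite), and a graph with no reachable pairs at all is
assigned ASPL 0. Note that removal of even a peripheral node changes the
ASPL of the remainder — a uniform star with $n$ leaves has ASPL
$2dn/(n+1)$ — so the Z-profile contrasts are driven by *how much more* a
bottleneck matters, which the planted-bottleneck tests quantify.

Snapshot-level profiles can be averaged with `ensemble_average_profile()`
(ΔL averaged, then re-standardized; Z is scale-invariant, so profiles
differing only by a uniform factor agree). Whether one should average Z
over snapshots or profile a single merged-occupancy graph is genuinely
ambiguous in the source; the pipeline profiles the ensemble-averaged
graph, and the snapshot-averaging route is exposed for users who prefer
it.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| contact / interface cutoff | 5.0 | Å | edge and interface definition |
| occupancy threshold τ | 0.5 | fraction of frames | edge retention |
| λ | 0 | – | coevolutionary MI mixing weight |
| coupling clamp | [0.01, 1−1e−9] | – | caps edge distance at ln 100 |
| n_samples | 1000 | frames | ensemble averaging of the scan |
| perturbation mode | remove (pipeline) | – | node deletion vs coupling reweight |
| z_min | 1.0 | – | hotspot threshold |
| ENM cutoff | 12 | Å | spring network connectivity |
| ENM kT | 0.6 | energy | fluctuation scale (≈ kcal/mol at 300 K) |

`profile_perturbations()` itself defaults to reweight mode — the milder,
substitution-aware perturbation — while the pipeline defaults to
remove/ASPL, the classical centrality-style probe used for published
Z-score profiles.

## What the synthetic generator emulates — and what it does not

`sample_enm_ensemble()` draws frames from the Gaussian whose covariance
is $k_BT\,\Gamma^{+}$, the pseudo-inverse of an isotropic Kirchhoff
(Gaussian-network) stiffness matrix over Cα pairs within 12 Å; the rigid
null space is removed by eigenvalue thresholding at $10^{-8}$ of the
largest eigenvalue. The isotropic GNM form (three identical Cartesian
blocks) was preferred over a full anisotropic model because its DCCM is
analytic — $C_{ij} = \Gamma^{+}_{ij}/\sqrt{\Gamma^{+}_{ii}\Gamma^{+}_{jj}}$ —
giving every correlation estimator an exact oracle. Pseudo-side-chain
beads sit 1.5 Å off the backbone so the side-chain contact mode is
exercisable; they move rigidly with their Cα. `make_toy_complex()` places
two extended chains so that exactly the planted residues have heavy atoms
within 4.5 Å of the partner (all others > 5 Å away; with zero contacts
the chains are > 20 Å apart, and the then-disconnected spring network is
bridged by one weak spring between nearest Cα atoms so the null fixture
can still be sampled). `plant_bottleneck_graph()` joins dense clusters
through a single articulation node.

These fixtures have Gaussian, harmonic, memory-free dynamics: no
anharmonic transitions, no side-chain rotamers, no solvent, and planted
rather than evolved interfaces. Passing tests therefore demonstrate that
the estimators and graph algorithms are *correct* — they converge to
analytic truth and agree with brute-force enumeration — not that the
biological conclusions drawn from any particular real trajectory are
right.

## Numerical choices

- Zero-fluctuation residues yield zero off-diagonal correlation (with a
  warning) instead of NaN, keeping graph construction total.
- Singular 3×3 marginal covariances give a generalized correlation of 0
  with a warning.
- Co-minimal shortest paths are counted with a relative tolerance of
  $10^{-9}$ in the enumeration oracle; `shortest_path()` breaks ties by
  lexicographic node label so returned paths are reproducible.
- Stride subsampling picks frames $\lfloor kF/n \rfloor$, $k = 1..n$
  (always including the last frame); random subsampling requires an
  explicit seed.
- Altloc records keep the highest-occupancy conformer, ties broken by
  altloc letter; solvent and common ions are dropped with a logged count;
  hydrogens are retained but flagged and excluded from heavy-atom
  contacts.
- The test and acceptance problem sizes (50-residue/5000-frame DCCM
  convergence, ≤ 8-node enumeration oracles, 50 dumbbell seeds, a
  290-residue/1000-frame end-to-end complex) were chosen as the smallest
  instances at which sampling error is comfortably below the asserted
  tolerances.

## Known limitations

- The built-in contact scorer is intentionally simple; absolute ΔΔG
  values are not comparable to trained statistical potentials, only the
  averaging framework around the scorer is validated.
- MM-GBSA energies are not computed; only externally produced per-residue
  decomposition tables are aggregated.
- The coevolutionary MI normalization (min–max over observed pairs) is a
  pragmatic choice; no standard exists.
- Entropy contributions, folding-stability ΔΔG, time-lagged correlations,
  Markov state models and path-ensemble analyses are out of scope.
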