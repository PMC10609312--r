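---
title: "Coarse-grained allostery analysis of amino-acid binding proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained allostery analysis of amino-acid binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The scientific problem

Periplasmic amino-acid binding proteins (AABPs) such as the glutamine
binding protein (GlnBP), the histidine binding protein (HisJ) and the
lysine/arginine/ornithine binding protein (LAOBP) of *E. coli* capture
their substrate between two lobes — a large "Thumb" and a smaller "Index
Finger" joined by two short hinge segments — and close on it like a hand
grasping a ball. `allonet` implements a coarse-grained analysis chain for
this open-to-closed transition:

1. sequence comparison of the family and a consensus numbering (1–238)
   for all cross-protein statements;
2. Gaussian (GNM) and anisotropic (ANM) elastic network models on
   C-alpha structures: fast/slow fluctuation profiles, hot spots,
   hinges, cross-correlation maps and open-to-closed mode overlaps;
3. a desk-scale neural relational inference (NRI) variational
   autoencoder that learns a discrete interaction graph from
   coarse-grained trajectories;
4. shortest-path analysis of allosteric signalling from the conserved
   substrate-recognition residues (consensus 11 and 117) to the I-Loop
   (consensus 98–112), the terminal receiver of the signal;
5. a per-residue binding-energy filter on MM-GBSA-style decomposition
   tables (key residues have totals below −1.00 kJ/mol).

A synthetic-data module generates every input the pipeline needs —
two-lobe hinge structures, elastic-network-sampled trajectories,
spring-particle benchmarks with known connectivity, and synthetic energy
tables — so the whole chain runs and is tested without downloads.

## Elastic network models

Both network models place one node per residue at its C-alpha position
and join residue pairs within a cutoff by identical springs.

**GNM.** The topology is the N×N Kirchhoff matrix: off-diagonal entries
are −1 for contacts within the cutoff (default 7.3 Å), diagonals are the
contact degrees, so rows sum to zero. Residue fluctuations and
cross-correlations are proportional to the pseudoinverse, restricted to
selected eigenmodes:

* *slow modes* (default: 2 lowest nonzero) describe collective domain
  motion; their near-zero minima are mechanical hinges;
* *fast modes* (default: 10 highest) reflect local packing; their minima
  are kinetically "hot" residues implicated in stability and
  recognition.

The mode counts are configurable; the defaults reflect common practice
and the two-lobe geometry of these proteins, where two slow modes
capture cleft opening and inter-lobe torsion. The thermal prefactor
3k_BT/γ defaults to 1, so profiles are in relative units. Zero modes are
identified at a relative eigenvalue tolerance of 1e-8 (double-precision
eigensolver noise); disconnected contact graphs produce one extra zero
mode per component and are flagged.

**ANM.** The 3N×3N Hessian is assembled from 3×3 super-elements
−(γ/R²)·ddᵀ per contact (the second derivative of the harmonic pair
potential at equilibrium); the cutoff defaults to 15 Å, the community
standard for C-alpha ANM — isotropic 7.3 Å networks are under-determined
in 3N dimensions. The six rigid-body modes are excluded from every
derived quantity. Mode overlap with an observed transition,
|v_k·Δr|/(|v_k||Δr|) after Kabsch superposition, quantifies how much of
the open-to-closed difference vector a mode explains; superposition
removes the rigid-body contamination that visual comparisons ignore.

On idealized synthetic geometry the two models agree on *flexibility*
but not mode-by-mode: shell-like lobes give nearly flat GNM profiles,
and single ANM bending modes have interior nodes, so the cross-model
consistency check in the test suite compares full-spectrum mean-square
fluctuations on a randomly packed globular cluster (Spearman rank
r > 0.5, typically ≈ 0.9) rather than single-mode amplitudes.

## Trajectory statistics

`kabsch_superpose()` implements the SVD solution of the least-squares
superposition problem (with reflection correction); `rmsd_series()` and
`rmsf_profile()` build on it. The RMSF reference is the mean structure,
iterated once — the choice matters little for converged sampling and is
fixed for reproducibility. NRI node features are the standard
6-dimensional ones: position and velocity in x, y, z, standardized per
dimension with the transform recorded; velocities fall back to central
finite differences when a trajectory carries none.

## The relational-inference model

The NRI component is a variational autoencoder over K discrete edge
types (default 4) per ordered node pair:

* **encoder**: each node's whole feature window is embedded by a tanh
  layer; ordered pair embeddings pass through a second tanh layer to K
  logits — one message-passing round, deliberately smaller than the
  reference architecture of the method family;
* **sampling**: Gumbel-softmax (concrete) relaxation at temperature 0.5,
  so edge choices stay differentiable;
* **decoder**: a teacher-forced multi-step rollout (default 10 steps):
  from a data frame the state advances by its own predictions, each step
  summing per-pair messages gated by the sampled edge type (type 1 sends
  nothing under the no-edge convention) into a zero-initialized output
  layer, so an untrained model predicts persistence;
* **objective**: ELBO = Gaussian log-likelihood of the rolled-out
  features (fixed variance σ² = 5e-5) − KL(q(z|x) ‖ uniform over K),
  maximized with minibatch Adam; gradients are derived by hand and
  verified against central finite differences in the test suite.

Four design choices deserve explanation because the obvious alternatives
fail quietly:

* **Multi-step rollout.** With one-step prediction the ELBO is almost
  independent of the graph: persistence plus a local correction explains
  one step well. Errors from wrong edges compound over a rollout, which
  is what makes the graph identifiable.
* **Small reconstruction variance.** At unit output variance the KL term
  dominates the per-pair reconstruction preference and the posterior
  collapses to uniform. σ² = 5e-5 follows reference implementations of
  this model family.
* **Linear messages (default).** Coarse-grained fluctuations are
  near-harmonic, so forces are linear in pair features. A tanh message
  MLP is expressive enough to infer a *fixed* adjacency from
  instantaneous pair features (connected pairs sit closer and move
  together), which bypasses the edge variables entirely; linear messages
  close that loophole. `decoder = "tanh"` remains available.
* **Ensemble training.** From a single system with one fixed graph the
  decoder can absorb the graph into its weights no matter how it is
  regularized — we verified that a decoder warmed under all-edges-on
  gating values false-pair messages as much as true-pair ones, so no
  local gradient favours the truth. `train_nri()` therefore accepts a
  list of systems (spring simulations with different random graphs, the
  design of the original relational-inference benchmark); the encoder
  must then read each window's graph from the data, and connectivity
  recovery on 5-particle systems is essentially exact. For a single
  protein system the learned posterior is reported as what it is — a
  window-averaged coupling summary — and the pathway stage can fall back
  to GNM correlations.

Training occasionally lands in a poor local basin whose ELBO per window
sits far below that of a converged run; `train_nri()` therefore supports
independent restarts with selection by the final ELBO — a label-free
safeguard that uses only the training objective.

For binary connectivity benchmarks K = 2 with the no-edge convention is
used (the ground truth is binary); K = 4 stays the general default for
domain-interaction maps. Blocks of 10 consecutive residues (238 residues
→ 24 blocks) keep the O(M²) pair set desk-scale; block labels map to the
eight consensus domains by majority.

## Allosteric pathways

The residue-interaction graph connects spatial contacts only, weighted
by −log(coupling) with coupling either |GNM correlation| or the NRI
any-edge probability (clipped to [ε, 1−1e-9], ε = 1e-4): strong coupling
gives near-zero weight, so minimum-weight paths are maximum-coupling
signalling routes. One shortest path per (source, sink) pair is computed
by Dijkstra with fully deterministic tie-breaking (fewer hops, then the
lexicographically smallest sequence). Sources default to consensus 11
and 117; sinks default to the I-Loop (98–112; the shifted 97–111 reading
is available). Residue occurrence frequency across the path set ranks
relay residues; the "most likely pathway" maximizes mean member
frequency with weight and lexicographic tie-breaks, so it is invariant
to path-set order.

## Binding-energy tables

The energetics module is deliberately table algebra: the MM-GBSA
computation itself requires all-atom trajectories and is out of scope.
Tables carry per-residue van der Waals, electrostatic, polar and
non-polar solvation terms and the total, in kJ/mol, with "value ± sd"
cells and Unicode minus accepted. Recomputed totals (component sums,
rounded to 2 decimals) are compared against printed totals at a
documented tolerance of ±0.03 kJ/mol — published tables round each
component, and one LAOBP row in the packaged reference table differs
from its component sum by 0.05 kJ/mol, an inconsistency we report rather
than repair. "Lower than −1.00" is read as a strict inequality. The
packaged reference table transcribes the published decomposition for the
GlnBP–Gln, HisJ–His and LAOBP–Lys complexes.

## What the synthetic generator emulates — and what it does not

`make_two_domain_structure()` builds two self-avoiding globular lobes
(beads walked at 3.8 Å spacing along a spherical spiral whose winding
separation also comes out near 3.8 Å) joined by a hinge-bowed linker
with a small helical offset; the offset exists because a perfectly
straight linker would leave lobe torsion about the inter-lobe axis as a
spurious near-zero mode. Defaults give a 238-residue system (115 + 8 +
115) with an open hinge angle of 120°; `close_hinge()` rotates one lobe
rigidly about the hinge axis, and the pipeline's closed default of 60°
brings the lobe surfaces within the GNM cutoff, as substrate-mediated
contacts do in the real closed state.

`sample_enm_trajectory()` draws frames as random superpositions of
internal elastic-network modes with equipartition variances
(amplitude/λ). Two deliberate departures from the naive recipe: a
per-mode per-residue RMS cap (default 1.5 Å) stands in for the anharmonic
restraints that keep real soft-mode excursions finite — without it the
softest synthetic modes produce ~40 Å displacements — and the GNM-source
sampler projects rigid-body components out of its displacement basis,
since superposition removes them from any real trajectory. AR(1) time
correlation (coefficient 0.9) makes finite-difference velocities
informative; parameter-recovery tests use independent frames because
AR(1) sampling at coefficient 0.9 leaves only ~5% effective independent
frames for variance estimation.

`simulate_springs()` is a velocity-Verlet integrator for unit-mass
particles with zero-rest-length springs on a random graph, recorded in
the centre-of-mass frame with a weak common tether (0.1) bounding
unbound particles — the role the bounding box plays in the original
relational-inference benchmark. Defaults (k = 1, dt = 0.005, record
every 40 steps) make one recorded step ≈ 5% of a pair oscillation
period, large enough that neighbour forces are visible in one step.
Energy drift above 1% over a run aborts as an unstable timestep.

What passing tests on these stand-ins do **not** show: agreement with
the published sequence statistics (70.46%/28.38%/30.67% identity, 52
conserved columns) or the structure-specific GNM landmarks (hot spots at
consensus 18/116, hinges at 89/193), which are properties of the real
crystal structures and database sequences. Those inputs are not
redistributable inside the package; the corresponding acceptance checks
run on clearly-labelled synthetic stand-ins and fail honestly where a
stand-in cannot carry the published value. With the real PDB and FASTA
files supplied, the same functions compute the published quantities
directly.

## Problem sizes and numerical choices

The test-suite and acceptance computations use 238-residue synthetic
systems, trajectories of 150–1000 frames (5000 for per-mode variance
checks on a 40-node cluster), and spring ensembles of six 5-particle
systems with 2000 recorded frames each, trained for 60 epochs — sizes
chosen so the complete chain, including training, reruns in minutes on
one core. Eigen-decompositions use LAPACK via `eigen(symmetric = TRUE)`;
alignments use Biostrings (BLOSUM62, gap open 11, extend 1 — BLAST
defaults, since the family analysis named the tool but not parameters);
identity is reported BLAST-style over the trimmed alignment core.
The three-way progressive alignment aligns the closest pair first and
the third sequence against the pair's column profile with the same
affine-gap scheme (profile columns score the mean substitution score,
gap entries contributing the extension penalty).

## Known limitations

* Elastic-network results on shell-like synthetic lobes have flatter
  GNM profiles than real, densely packed domains; landmark-residue
  positions are not reproducible on stand-ins.
* Single-system NRI posteriors summarize coupling but are not validated
  connectivity estimates; validated recovery requires ensembles.
* The pathway edge-weight rule (−log coupling on contacts) is one
  defensible operationalization; the underlying study leaves its
  weighting unstated.
* Insertion-coded residues are kept in file order; crystal gaps are kept
  missing, and the network is built on resolved C-alphas only.
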