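# allonet

Coarse-grained allostery analysis of bacterial amino-acid binding
proteins (AABPs) in R.

Periplasmic binding proteins such as GlnBP, HisJ and LAOBP capture their
amino-acid substrate between a large lobe (the "Thumb") and a small lobe
(the "Index Finger") joined by two hinge segments, closing on it like a
hand around a ball. `allonet` implements the computational chain used to
dissect that open-to-closed transition at residue resolution:

* **Sequence layer** — pairwise and three-way progressive alignment
  (BLOSUM62, affine gaps), percent identity/coverage, conserved columns,
  and the consensus numbering (1–238) used for every cross-protein
  statement.
* **Elastic networks** — the Gaussian network model (Kirchhoff matrix
  `Γ`, fluctuation profiles `MSF_i ∝ Σ_k v_ki²/λ_k`, cross-correlation
  maps from the mode-restricted pseudoinverse, hot-spot and hinge
  detection) and the anisotropic network model (3N×3N Hessian of
  super-elements `−(γ/R²) d dᵀ`, directional modes, and overlap
  `|v_k·Δr|/(|v_k||Δr|)` with the open→closed transition).
* **Relational inference** — a desk-scale neural relational inference
  VAE over K discrete edge types: window encoder → Gumbel-softmax edge
  sampling → multi-step message-passing decoder, trained by maximizing
  `ELBO = E_q[log p(x|z)] − KL(q(z|x) ‖ p(z))` with hand-derived
  gradients; residue blocks aggregate to 8×8 domain-interaction maps.
* **Allosteric pathways** — residue graphs weighted by `−log(coupling)`
  on spatial contacts, deterministic Dijkstra shortest paths from the
  substrate-recognition residues (consensus 11, 117) to the I-Loop
  (98–112), residue occurrence frequencies and the most likely pathway.
* **Binding energetics** — per-residue MM-GBSA-style decomposition
  tables (`E_VDW + E_ELE + E_GB + E_GBSUR = E_TOT`, kJ/mol), recomputed
  totals and the key-residue filter (`E_TOT < −1.00` kJ/mol), with the
  published decomposition for the three AABP–substrate complexes
  packaged as a reference table.
* **Synthetic data** — two-lobe hinge structures at C-alpha resolution,
  elastic-network-sampled trajectories, spring-particle benchmarks with
  known connectivity, and energy tables with planted key residues, so
  the whole pipeline runs and is tested without any downloads.

## A worked example

```r
library(allonet)

open   <- make_two_domain_structure(seed = 1)   # 238-residue synthetic AABP
closed <- close_hinge(open, 60)

g <- gnm(open)                                  # Gaussian network, 7.3 A
iA <- which(open$region == "lobeA"); iB <- which(open$region == "lobeB")
C <- cross_correlation(g, "slow", 2)
mean(C[iA, iB])
#> [1] -0.9992161

a  <- anm(open)                                 # anisotropic network, 15 A
ov <- overlap_with_transition(a, ca_coords(open), ca_coords(closed))
sum(ov$overlap[1:3]^2)
#> [1] 0.8573566

paths <- contact_adjacency(ca_coords(open), 7.3) |>
  (\(ct) build_graph(abs(cross_correlation(g, "all")), ct))() |>
  allosteric_paths(sources = c(11, 117), sinks = iloop_positions())
top_pathway(paths)$path[[1]]
#> [1] 117 116 103

et <- compute_etot(read_energy_table(aabp_energy_table_path()))
key_residues(et)[1:3, c("system", "consensus", "residue", "e_tot")]
#> # A tibble: 3 × 4
#>   system consensus residue e_tot
#>   <chr>      <int> <chr>   <dbl>
#> 1 GlnBP        117 K115    -6.1
#> 2 GlnBP        161 D157    -2.04
#> 3 GlnBP         69 A67     -1.64
```

The slow-mode inter-lobe correlation of −0.999 is the open state's
anticorrelated, cleft-opening motion; 86% of the closure displacement is
captured by the three lowest internal modes; the most likely signalling
pathway runs from recognition residue 117 into the I-Loop (residue 103);
and the most favourable binding residue of the GlnBP–Gln complex is
consensus 117 (K115) at −6.10 kJ/mol.

`run_pipeline(pipeline_config(...))` executes the whole chain —
structures → alignment → GNM → ANM → trajectory → relational inference →
pathways → energetics — with one global seed and a reproducibility
manifest.

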