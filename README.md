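# caimnet

Longitudinal network analysis of spontaneous activity in two-photon calcium
imaging. The package targets experiments in which the same population of
cortical neurons is imaged repeatedly over days to weeks: each session yields
fluorescence traces for tracked cells, and the scientific questions are how
those cells organize into functional modules, how stable that organization is
from day to day, and whether a subset of cells forms a persistently coupled
temporal core.

It is intended for systems neuroscientists analysing multi-session
spontaneous-activity recordings, and for methodologists who need a tested,
seedable implementation of the full chain with a synthetic-data generator for
validation.

## What it computes

1. **Jitter-null correlation networks.** Traces are first-differenced and
   correlated (Eq. `W_ij = Σ_t (x_i − μ_i)(x_j − μ_j) / σ_i σ_j` on the
   differenced series); each pair is tested against surrogates in which both
   cells' traces are independently jittered (random start index in the first
   2 s, keeping the centred `T − 2p` segment), giving a signed z-scored
   matrix `W` and a sparse binary adjacency `A = [P < 0.05]`.
2. **Hierarchical modules.** Multi-resolution modularity maximization,
   `Q(γ) = Σ_ij [A_ij − γ k_i k_j / 2m] δ(g_i, g_j)`, with recursive splits
   retained only when they beat degree-preserving rewired nulls (p < 0.05);
   spatial compactness of each module as a permutation z-score of
   nearest-same-module-neighbour distance.
3. **Similarity decay.** For each session pair, Pearson similarity of the
   shared-cell upper triangles of `W` (or of module co-assignment matrices),
   standardized by a Mantel-style row/column permutation null, then
   correlated against day distance.
4. **Multilayer dynamics.** Multilayer modularity
   `Q(γ, ω)` with per-layer degree nulls and ordinal interlayer coupling;
   node flexibility `f_i` (fraction of adjacent-session label changes)
   rank-averaged over uniform samples from the feasible (γ, ω) box.
5. **Temporal core-periphery.** Consistency matrix `G_ij` (fraction of
   sessions an edge persists), sigmoidal coreness template
   `C*_m = 1/(1 + exp(−(m − βN) tan(πα/2)))` fitted by simulated annealing
   to maximize `R = Σ_ij G_ij C_i C_j`, a 31 × 31 (α, β) grid against a
   weight-shuffled null, and core-versus-periphery stability contrasts.
6. **Synthetic studies.** A generator with planted hierarchical modules,
   spatial layout, session-to-session drift, dropout, and a stable core,
   plus ground truth for parameter-recovery testing.

## Worked example

```r
library(caimnet)
set.seed(1)
cfg <- synth_config(n_cells = 80, n_sessions = 5, day_offsets = c(0, 3, 7, 10, 14),
                    n_frames = 900, noise_sd = 0.4,
                    signal_strength_per_level = c(0.45, 0.8),
                    core_fraction = 0.2, drift_prob_per_day = 0.1, seed = 1)
study <- generate_study(cfg)
nets  <- lapply(study$sessions, build_network, n_jitter = 200)
nets[[1]]
#> <correlation_network> session_01 (day 0): 73 cells, edge density 0.400 (alpha 0.05, 200 jitters)
```

73 of the 80 cells survived dropout in session 1, and 40% of cell pairs have
correlations stronger than their jitter null at α = 0.05.

```r
hp <- hierarchical_sweep(nets[[1]]$A, n_runs = 20, n_null = 50)
hp
#> <hierarchical_partition> 2 significant level(s)
#>   level 1: 2 modules (gamma 0.25, p <= 0.020)
#>   level 2: 4 modules (gamma 0.88, p <= 0.020)
spatial_compactness(hp, study$ground_truth$positions[nets[[1]]$cell_ids, ],
                    n_perm = 500)
#> <spatial_stats> 6 module(s), 500 permutations
#>   median z: -2.67
#>   Spearman rho(z, level): -0.41
```

The planted 2 × 2 hierarchy is recovered — two coarse modules each splitting
into two, all splits passing the rewiring null — and modules are far more
spatially compact than chance (median z = −2.67).

```r
tab <- session_similarity(nets, kind = "correlation", n_perm = 500)
decay_analysis(tab)
#> <decay_result> r(z, day distance) = -0.905 over 10 pairs

ml   <- build_multilayer(nets)
core <- anneal_coreness(consistency_matrix(ml), alpha = 0.9, beta = 0.8)
core
#> <coreness_result> 48 nodes, alpha 0.9 beta 0.8, R = 91.0823, 10 core node(s) at midpoint
fl <- sample_flexibility(ml, n_samples = 200)
flexibility_vs_coreness(fl, core)
#> [1] -0.5440578
```

Network similarity decays steeply with the number of days between sessions
(r = −0.90 across the 10 session pairs). On the 48 cells present in all five
sessions, the annealed core-periphery fit flags 10 cells as the persistent
core, and cells with high coreness are systematically the least flexible in
the multilayer module partitions (Spearman ρ = −0.54) — the stable-core /
variable-periphery signature.

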