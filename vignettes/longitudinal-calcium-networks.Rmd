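---
title: "Methods: longitudinal network analysis of spontaneous calcium-imaging activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal network analysis of spontaneous calcium-imaging activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`caimnet` analyses spontaneous-activity recordings of the same population of
cortical neurons imaged repeatedly over days to weeks: per-session
fluorescence trace matrices (cells x frames, ~30 Hz, ~10 minutes), a table of
tracked cell identities with 2-D positions in micrometres, and integer day
offsets. This vignette explains the models and procedures the package
implements, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where the
design was genuinely open.

## 1. Network reconstruction with a jitter null

Fluorescence traces carry strong serial autocorrelation from the slow decay
of the calcium indicator, so raw Pearson correlations are confounded by
within-cell dynamics. Each trace is therefore first-differenced
(`x[t+1] - x[t]`, length `T - 1`), and the session's cell-by-cell matrix
`R_raw` is the Pearson correlation of the differenced traces.

An observed correlation is declared an edge only if it beats a *jitter null*:
in each of `n_jitter = 1000` repetitions every cell independently draws a
start index `p` uniformly from the first two seconds of the recording
(`{0, ..., 60}` at 30 Hz) and keeps the centred segment of length `T - 2p`,
destroying fine temporal alignment between cells while preserving each
trace's marginal statistics. Surrogates are differenced exactly like the
originals. The empirical two-sided p-value uses a pseudocount,
`P = (1 + #{|r_jitter| >= |r_obs|}) / (1 + n_jitter)`, so it can never be
exactly zero; the signed, weighted matrix `W` standardizes `r_obs` against
the jitter distribution, `(r_obs - mean) / sd`. Binary edges `A = [P < 0.05]`
feed the module and core-periphery analyses; `W` feeds the similarity
analyses. Because Pearson correlation is affine-invariant per cell, the whole
pipeline is invariant to any per-cell scaling of fluorescence (ΔF/F or raw
units).

Numerical conventions worth stating:

* Within one jitter repetition, all cells' surrogates are truncated to their
  common (minimum) length before differencing and correlating, so each
  pair's null correlation is computed on the overlapping differenced
  segment with a single pass per repetition.
* The test is two-sided on `|r|`; anticorrelations are meaningful and `W` is
  signed.
* For two *identical* traces the draw `p_i = p_j` reproduces `|r| = 1`
  exactly, so `P` sits marginally above its floor `1/(n_jitter + 1)`; the
  edge is of course retained.

## 2. Single-session module hierarchy

Modules are found by modularity maximization. The quality function is
evaluated exactly as

Q(γ) = Σ_ij [A_ij − γ k_i k_j / 2m] δ(g_i, g_j),

summed over ordered pairs with the `i = j` term kept in the degree-null part
(and `A_ii = 0`). No `1/2m` prefactor is applied; positive scaling does not
change the argmax, and this convention yields the clean identity that the
one-module partition has `Q = 0` exactly at `γ = 1` — used as a test
invariant. Maximization is a greedy Louvain scheme on the dense modularity
matrix (local moving with strict-gain moves, then agglomeration, iterated to
convergence), run over `n_runs = 100` random node orders with the best
partition kept; the result is additionally floored at the all-singletons and
one-module partitions. Ties in local moves keep the current community, so a
run is deterministic given its visiting order.

The hierarchy is built recursively. The whole network is scanned over an
increasing resolution grid (`γ = 0.25, 0.5, ..., 4`) until the coarsest `γ`
at which maximization splits it. The split is kept only if its modularity
exceeds the same maximized statistic on 100 degree-preserving rewired graphs
(`p < 0.05`, pseudocounted); nulls are maximized with the *same* number of
restarts as the observed graph so the comparison is calibrated. Each
retained module is then re-examined on its induced subgraph from the same
resolution upward, and recursion stops where no significant split exists or
a module falls below `min_size = 4`. Only the first splitting resolution of
each subgraph is tested, which keeps the per-branch false-positive rate at
the nominal level rather than accumulating it across the grid; on
Erdős–Rényi graphs the procedure returns no hierarchy in ~95% of runs.
Levels are integers 1..L, coarse to fine, and every reported level has
passed the null test. The exact multi-resolution recipe published for this
class of analyses is not restated anywhere in full; this recursive scheme is
the package's own concrete instantiation and is documented as such.

Spatial statistics: for every module, the mean distance of each member to
its nearest same-module cell is compared with the distribution obtained by
uniformly permuting all cell positions (module assignments fixed,
`n_perm = 1000`), and reported as a z-score — negative z means the module is
more spatially compact than chance. Across a hierarchy the Spearman
correlation of z with level summarizes whether deeper (smaller) modules are
more compact. A module spanning all cells is permutation-invariant and gets
`z = 0` by convention; singleton modules are skipped with a warning.

Co-assignment consensus: `C_ij` is the fraction of an ensemble of partitions
in which cells i and j share a module. The analysis-scale ensemble is 10000
single-layer maximizations with resolutions drawn uniformly from
`[0.5, 3]`; tests and the bundled acceptance script use 100–200.

## 3. Day-to-day similarity and its decay

For a session pair (u, v), both matrices are restricted to the cells present
in both sessions (pairs sharing fewer than 10 cells are skipped — Pearson
similarity over fewer than 45 edge pairs is unstable). The strictly upper
triangles are vectorized and correlated, giving `r_uv`; the diagonal never
enters. Significance is assessed Mantel-style: the rows and columns of one
matrix are permuted by the same random node permutation (`n_perm = 1000`)
and `r` recomputed, and `z_uv = (r_obs - null mean) / null sd`. The
permutation null is applied to `W_u` against the *other* session's matrix;
permuting a matrix against itself would not be a null for `r_uv` at all.
Since the statistic is asymmetric in which matrix is permuted, both
orderings are computed and their mean reported alongside each.

The decay analysis correlates `z_uv` with the day distance `d_uv` (from the
metadata's integer day offsets, not session indices) across all usable
pairs, separately for correlation matrices (`W`) and co-assignment matrices
(`C`). The tercile analysis groups each session's hierarchy levels into
three contiguous depth bands, recomputes co-assignment within each band, and
repeats the decay analysis per band; sessions with fewer than three levels
collapse to a single band with a warning. Raw co-assignment values in
`[0, 1]` are used throughout (no thresholding).

## 4. Multilayer modules and flexibility

The first five sessions (configurable) are bound into a multilayer network
over the cells present in *all* of them. Multilayer modularity couples each
cell to itself in adjacent layers (ordinal coupling, matching the temporal
ordering of sessions; all-pairs coupling is available behind a flag):
intra-layer terms use each layer's own degree null `A_iju − γ k_iu k_ju /
2m_u`, and the coupling term adds ω for every ordered adjacent-layer pair in
which a cell keeps its label, so a labeling constant across layers
contributes `2ωN(T−1)`. Maximization runs the same Louvain core on the
supra-matrix of (cell, layer) nodes; labels share one namespace across
layers, so per-cell flexibility is simply the fraction of adjacent-layer
transitions at which the label changes.

Because γ controls module size and ω cross-layer persistence, results are
aggregated over a bounded region of the (γ, ω) plane rather than a single
point. The feasible region is where maximization yields informative
structure: more than one community, fewer than `N × T`, and mean flexibility
strictly between 0 (uniform across layers) and 1 (maximally dissimilar).
The box is found by probing a coarse grid, taking as reference the feasible
point whose flexibility is farthest from the degenerate boundaries, bisecting
each axis to the feasibility boundary with the other parameter held at its
reference/midpoint value, and finally shrinking any box end whose corner
fails until all four corners pass. Feasibility at a point is decided by
majority over three independent maximizations: single stray partitions
otherwise extend the box deep into regimes that are only degenerately
feasible (e.g. very high γ, where every cell is its own cross-layer chain
and flexibility hovers at numerical zero). `sample_flexibility()` then
draws `n_samples` uniform (γ, ω) pairs from the box (analysis default
10000; tests and the acceptance script use 200), maximizes at each, ranks
the per-cell flexibilities within each sample, and averages the ranks —
rank-averaging makes the profile robust to the overall flexibility scale
varying across the box.

## 5. Temporal core-periphery structure

The consistency matrix `G_ij` is the fraction of layers in which edge
`(i, j)` is present. Coreness assigns to the nodes a permutation of the
sigmoidal template

C*_m = 1 / (1 + exp(−(m − βN) · tan(πα/2))), m = 1..N,

where α sets the sharpness of the core-periphery transition (α = 1 is the
binary step, implemented as the limit since tan(π/2) is undefined) and β the
core size (β from 0 to 1 shrinks the core from N to 0). The assignment
maximizes `R = Σ_ij G_ij C_i C_j` by simulated annealing over pairwise
swaps: initial temperature calibrated so a typical uphill-cost move is
accepted with probability ~0.8, geometric cooling ×0.95 per sweep, `N²`
proposals per sweep, stop after 50 sweeps without improvement, greedy
swap-polish at the end, best of 10 restarts (the first restart starts from
the strength ranking, the rest at random). On matrices of up to 8 nodes the
annealer provably attains the factorial-search optimum in the test suite.
`R` on the unnormalized template is reported; a normalized variant (scaling
C so Σ_ij C_i C_j = 1, which rescales R by a positive constant at fixed
(α, β) without changing the optimal assignment) is available via
`normalize = TRUE` for cross-parameter comparability.

The parameter plane is explored on a 31 × 31 grid of (α, β) in `[0, 1]²`
(961 points). At each point the observed annealed `R` is compared with the
mean over `n_null = 100` *weight-shuffled* copies of `G` (off-diagonal
entries permuted uniformly and symmetrized) annealed with identical
settings, giving `delta_R`; the top 10% of points flag the regimes where the
observed core most exceeds chance. The null had to be chosen with care: a
null that merely relabels nodes (permuting G's rows and columns) is inert
here, because the annealer already searches over all assignments of the
template to nodes — relabeling only permutes the search space and returns
the same optimum, making `delta_R` identically zero for every matrix.
Shuffling the weights instead preserves the consistency distribution while
destroying which pairs carry persistent edges, which is the structure the
core model claims.

Downstream comparisons: the top 10% of cells by coreness (configurable)
form the core for the stability contrast — the similarity-decay analysis is
run on submatrices restricted to core cells and, separately, to the rest; a
stable core shows a weaker (less negative) decay. A core group below 4
cells is flagged as unstable to estimate. The midpoint rule
(coreness > 0.5) is also reported on every fit. Finally, the Spearman
correlation of rank-averaged flexibility against coreness quantifies the
expected inverse relation between the two stability measures.

## 6. The synthetic-data generator

`generate_study()` emulates the study design the pipeline targets:
50–250 tracked cells, several sessions spread over days to weeks,
hierarchically modular correlation structure, spatially compact modules,
partial cell overlap between sessions, gradual reorganization, and a small
persistent core.

Mechanics: cells are assigned (balanced, at random) to the finest modules of
a branching hierarchy (default `2 × 2`). Per session and per hierarchy
level, every module gets an independent latent signal — Gaussian noise
smoothed with a ~0.5 s moving average and scaled to unit variance — and a
cell's trace is the weighted sum of its modules' latents plus white
observation noise. Moving-average latents are essential: white-noise latents
would lose their cross-cell correlation under the differencing step, whereas
smoothed latents keep the differenced traces correlated. Module positions
are drawn once (uniform module centres in the field of view, Gaussian
within-module scatter), and positions are fixed across sessions because
cells are tracked. Between sessions, each non-core cell is redrawn to a
random finest module with probability `drift_prob_per_day × day gap`
(capped at 1), staying under its coarse parent with probability 0.8 so the
hierarchy persists while similarity decays. Core cells never move, and the
core *fills finest modules in order* rather than scattering across them: a
temporal core is defined by stable mutual coupling, and scattered singleton
core cells would have no persistent partners to be stable with. Dropout
removes each cell from each session independently; the generator redraws
the pattern (up to 100 attempts) so every session pair shares at least 10
cells. All randomness flows from one base seed with fixed per-stage
offsets, so output is bit-reproducible.

Default parameters describe a full-scale study: 150 cells, 5 sessions on
days 0/3/7/10/14, 18000 frames at 30 Hz, mixing weights (0.55, 0.7), unit
noise, 15% core, drift 0.05/day, dropout 0.1, 40 μm module scatter in a
500 μm field. The weights were chosen so that at the default recording
length the coarse-level coupling sits near the edge-detection threshold
while fine-level coupling is comfortably above it — this is what produces a
two-level *density* contrast in the thresholded adjacency, as a binarized
network otherwise saturates and hides the hierarchy.

What passing tests on this generator do and do not show: the latents are
Gaussian and stationary, whereas real somatic calcium signals are sparse,
nonnegative transients with occasional global (neuropil/state) components;
dropout is independent across cells and sessions, whereas real tracking
losses are spatially and temporally structured; drift is memoryless; and
every cell belongs to exactly one module per level. Recovery results
therefore validate the statistical machinery — calibration of the nulls,
correctness of the maximizers, sensitivity to planted structure at realistic
effect sizes — not the biological fidelity of any particular dataset.

## 7. Scaled-down study designs used by tests and the acceptance script

Re-simulating 18000-frame studies hundreds of times is unnecessary for
checking the method's properties, so the test suite and
`scripts/acceptance.R` use 900-frame recordings with proportionally
stronger planted contrast, chosen once as follows:

* *Hierarchy recovery*: 60 cells, weights (0.45, 0.8), noise 0.4 — the same
  near-threshold-coarse / strong-fine geometry as the full-scale defaults.
* *Similarity decay*: 100 cells, 5 sessions over 14 days, drift 0.05/day,
  dropout 0.1 (and drift 0 as the negative control).
* *Core recovery*: 100 cells, weights (0.3, 0.8), drift 0.15/day, dropout
  0.05, 20% core, fitted at (α, β) = (0.9, 0.8). The weak coarse weight
  keeps background consistency low (a near-threshold coarse background
  otherwise forms a large medium-consistency block that can outscore a
  small genuine core), and the low dropout keeps most of the planted core
  inside the all-session intersection that the multilayer analysis is
  restricted to. Recovery is scored against the core cells that survive
  that intersection, since no method can recover cells it never observes in
  all layers.
* Ensemble sizes are reduced (100–200 partitions, 200 (γ, ω) samples,
  100–500 permutations/nulls) relative to the analysis-scale defaults
  stated above.

## 8. Known limitations

* The hierarchy scheme tests only the first splitting resolution per
  subgraph; a structure that is non-modular at its coarsest informative
  scale but modular at finer scales would be missed.
* The (γ, ω) box is axis-aligned by construction; strongly curved feasible
  regions are represented conservatively.
* The coreness model fits a single core; multi-core structure shows up only
  as parametric variation across the (α, β) grid.
* Degenerate inputs are flagged rather than repaired: zero-variance
  differenced traces, zero jitter-null spread, constant similarity vectors
  and constant coreness all produce `NA` with warnings.
* With 5 layers, consistency values take only 6 levels, so ties in `G` are
  common; annealing restarts plus the greedy polish make the reported
  optimum reproducible, but the optimal *assignment* need not be unique.
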