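---
title: "Frustration, thermodynamics and energy landscapes of signed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frustration, thermodynamics and energy landscapes of signed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frustral)
```

## The model

A signed network is a simple undirected graph with edge signs
$J_{ij} \in \{+1, -1\}$ (activation / inhibition), zero diagonal, and — by
assumption — equal interaction magnitude on every edge. A perturbation is a
spin vector $s \in \{\pm 1\}^n$, and its cost is the Ising energy

$$h(s) = -\sum_{(i,j) \in E} J_{ij} s_i s_j,$$

each unordered edge counted once, so $h \in [-m, m]$ and $h(s) = h(-s)$.
Edges with $J_{ij} s_i s_j > 0$ are satisfied. A **gauge (switching)
transformation** $J'_{ij} = g_i J_{ij} g_j$, $g \in \{\pm1\}^n$, permutes
the energy spectrum (it maps $s \mapsto g \odot s$) and preserves the sign
of every cycle; the **frustration index** $\delta$ is the minimum number of
negative edges over all gauges, equal to the number of unsatisfied edges in
the ground state, with $h(s_\mathrm{ground}) = 2\delta - m$. A network is
balanced (the Jacobian sign pattern of a monotone system) iff $\delta = 0$,
iff no cycle has an odd number of negative edges.

Directed sign patterns are symmetrized before analysis: a pair
$(i \to j, j \to i)$ is compatible when the product of its signs is
nonnegative; incompatible pairs are removed and counted, and self-loops are
dropped (the order relations they induce are trivial). Stoichiometric
models enter through the sign structure of their Jacobian under mass-action
assumptions: for each reaction, every reactant activates the species it
net-produces and inhibits its co-reactants (it raises the rate of the
reaction consuming them); entries receiving opposite signs from different
reactions violate the constant-sign assumption and are excluded with a
count.

## Estimating the frustration index

Computing $\delta$ exactly is MAX-CUT-equivalent, so three routes coexist:

* `exact_frustration()` enumerates the $2^{n-1}$ gauge classes per
  connected component (vectorized in chunks; guard at 20 nodes per
  component).
* `minimize_frustration()` first runs the linear-time balance test on each
  component — balanced components are thereby solved *exactly*, which also
  guarantees perfect recovery on monotone inputs — and only then applies a
  seeded multi-restart simulated annealing in gauge space (single-node
  flips, geometric cooling from temperature 2 with ratio 0.95, 200 sweeps
  of $n$ proposals per restart) followed by greedy descent. The returned
  `delta_up` is always a valid upper bound; with 50 restarts it matched
  exact enumeration on at least 95 of 100 random test graphs with up to 14
  nodes and mean degree 3–6.
* `cycle_packing_lower_bound()` greedily extracts edge-disjoint frustrated
  cycles (each found by the balance test's sign-consistent traversal, then
  removed). Every such cycle forces at least one unsatisfied edge, so the
  count is a certified lower bound; when `delta_low == delta_up` the
  heuristic value is provably optimal, as happens on the yeast cell-cycle
  fixture (both 4).

`delta_max_bound()` returns $\min(\lfloor m/2 \rfloor,\, m - n + c)$ — the
trivial bound combined with the cycle rank, since a spanning forest is
balanced. The bound is deliberately topological (it ignores the sign
arrangement) and pluggable via its `fun` argument for users with sharper
bounds.

**Null models.** Significance of an observed $\delta_{up}$ is assessed
against sign reshuffles that preserve the edge skeleton and the count of
each sign. The Z-score convention is
$Z = (\bar\delta_\mathrm{null} - \delta_{up}) / \mathrm{sd}_\mathrm{null}$:
positive $Z$ means *less* frustrated than chance. P-values use the normal
tail on the observed side, consistent with replicate counts in the
hundreds-to-thousands. The per-node **sign-packing** test compares each
node's negative-edge count to a binomial with the network-wide negative
fraction (two-sided exact test, tabulated per degree class); the
network-level statistic is the number of significant nodes, scored against
the same reshuffled ensemble. Because that statistic is a small count on
small networks, its normal calibration is only trusted — and only tested —
in regimes where its null mean is well above one.

## Thermodynamics in the interaction strength β

With $p(s) = e^{-\beta h(s)} / Z(\beta)$ and
$Z(\beta) = \sum_s e^{-\beta h(s)}$, the parameter $\beta$ is read as the
energetic cost of one interaction (temperature is fixed); increasing
$\beta$ concentrates the response distribution on the ground states.
`exact_thermo()` enumerates all $2^n$ states ($n \le 20$), works in the log
domain throughout, and reports $\log Z$, $\langle h \rangle$ and the total
ground-state occupancy. At $\beta = 0$ the uniform average of $h$ is
computed as an integer mean so the zero is exact.

For larger networks `mean_field_solve()` uses a heterogeneous (degree
class) mean field, corrected for frustration: after the optimal gauge, the
degree $k$ of each class is replaced in the self-consistency equation by
$k_{pn}$, the class mean of (positive − negative) incident edges:

$$\langle s_{\sigma,k} \rangle = \tanh\!\big(\beta\, k_{pn}(k)\, \theta\big),
\qquad
\theta = \sum_\ell \frac{k(\ell)\, p_k(\ell)}{\langle k \rangle}\,
\langle s_{\sigma,k(\ell)} \rangle,$$

with the order parameter
$\langle s_\sigma \rangle = \sum_\ell p_k(\ell) \langle s_{\sigma,k(\ell)} \rangle$
and mean-field energy
$h_{mf} = -\tfrac{n}{2} \sum_\ell p_k(\ell)\, k_{pn}(\ell)\,
\langle s_{\sigma,k(\ell)} \rangle\, \theta$. These closed forms recover
the classical single-equation ferromagnet on all-positive regular graphs
(where the package's solution matches the scalar fixed point of
$x = \tanh(\beta k x)$ to $10^{-8}$) and satisfy
$h_{mf} \to 2\delta_{up} - m$ as $\beta \to \infty$, the same identity the
exact ground state obeys.

Numerical choices, all overridable:

* damped fixed-point iteration (damping 0.5), residual tolerance
  $10^{-13}$, cap $10^5$ iterations — the cap matters only near the
  transition, where the contraction rate approaches 1;
* default grid of 100 log-spaced $\beta$ in $[0.01, 5]$;
* symmetry breaking by initializing at $0.1$ and selecting the positive
  branch; each grid point warm-starts from the previous solution **floored
  at the initialization** — a pure warm start from a subcritical zero
  solution would pin the iteration at the trivial fixed point for every
  later $\beta$;
* `order_threshold()` reports the smallest $\beta$ with
  $\langle s_\sigma \rangle \ge 0.8$, refining the grid crossing by
  bisection (re-solving the self-consistency at each probe) to a $\beta$
  tolerance of $10^{-4}$. The 0.8 level is the conventional "ordered
  response" cutoff used throughout the package.

`metropolis_sample()` is the sampling counterpart: single-spin-flip
proposals at uniformly random nodes, acceptance
$\min(1, e^{-\beta \Delta h})$, one sweep = $n$ proposals, compiled core,
all randomness drawn from R's seeded RNG. Standard errors come from batch
means (20 batches by default), which absorbs the autocorrelation of the
chain at the moderate $\beta$ where the sampler is used as a check.

## Energy landscape

`collect_minima()` runs strict-decrease greedy descent (random-order
sweeps) from uniformly random states. Ties ($\Delta h = 0$) are rejected,
otherwise zero-cost plateaus could cycle forever; the fixed points are
therefore exactly the states where no single flip strictly decreases the
energy, the same predicate `is_local_minimum()` tests. Minima are
deduplicated as exact states — the global flip symmetry is *not* quotiented
out, and is instead handled at histogram time by the `fold_symmetry` option
of `pairwise_minima_distances()` (distance $d \mapsto \min(d, 1-d)$).
On dense balanced graphs the census collapses to the hidden ground state
and its flip; sparser balanced graphs legitimately hold additional strictly
local minima, which is why gauge-recovery claims are tested through the
balance test rather than through the census.

`interminimum_trajectory()` connects two states by flipping exactly the
differing spins in seeded random order (the path length equals the Hamming
distance), recording the energy at each step; whether a smarter flip order
would lower the barrier is deliberately out of scope, so the random order
is the documented convention. `average_gradient_profile()` averages the
per-step energy increments of many seeded random walks that never revisit a
flipped node, so step $d$ sits exactly at Hamming distance $d$ from the
start; the first increment from a local minimum is nonnegative by
definition, and the peak of the mean increment localizes the barrier rim
around the well.

## Synthetic data

The generators produce the contrasts the analysis is designed to detect,
with all randomness seeded and reproducible:

* `balanced_graph()` plants a hidden gauge $\sigma^*$ on a uniform random
  simple graph and sets $J_{ij} = \sigma^*_i \sigma^*_j$ — balanced by
  construction, with the hidden gauge recoverable up to one global flip per
  connected component.
* `random_signed_graph()` composes a degree model (uniform, or a
  stub-matching configuration model with self-/multi-edge rejection on a
  heavy-tailed sequence, topped up to the exact edge count), optional
  triadic-closure rewiring (`triangle_boost`, emulating the short-cycle
  enrichment of stoichiometric models), pendant nodes attached last
  (`leaf_fraction`, emulating the tree-like periphery of transcriptional
  networks), and a sign model: i.i.d. Bernoulli at skew 0, or per-node
  negative propensities from a two-point mixture whose spread is the skew
  (at skew 1 nodes are almost purely activator- or inhibitor-like). The
  mixture weight is chosen so the expected negative fraction equals the
  target at every skew.
* `random_reaction_system()` draws mass-action reactions with 1..`max_order`
  reactants and 1–2 products, no species on both sides.
* `yeast_cell_cycle_network()` returns the packaged 11-node cell-cycle
  fixture (provenance note alongside the data file); its documented
  statistics — 10 negative undirected edges, one incompatible directed
  pair, frustration index 4 — are re-derived by the test suite from the
  fixture, which validates the transcription.

What the generators do *not* emulate: curated large-scale networks'
community structure, degree–sign correlations beyond the two-point
propensity mixture, directed-motif statistics (feedforward loops), or any
database-specific curation bias. Tests passing on synthetic data therefore
validate the algorithms and their stated invariants, not field conclusions
about any particular organism's network.

## Problem sizes and test design

The suite checks every estimator against an independent route computed in
the spin basis through `energy()` alone (exhaustive state enumeration), at
sizes where enumeration is exact: heuristic-vs-exact on 100 random graphs
of up to 14 nodes; balance and gauge recovery on 20 planted graphs with
n = 200, m = 600; thermodynamic limits on all enumerable fixtures over a
100-point grid; Metropolis against exact Boltzmann frequencies
(total-variation distance below 0.05 at $10^6$ sweeps on 10 nodes) and
against exact internal energies on 20 twelve-node networks; and the
ordering of the 0.8-threshold $\beta$ between leafy (leaf fraction 0.4) and
triangle-boosted graphs of equal size and sign balance on 20 paired draws
(n = 250, m = 750). These sizes were chosen so each property is decidable
by exact computation or by comfortable Monte-Carlo margins.

## Limitations

* The annealing heuristic carries no optimality certificate beyond
  `delta_low`; for adversarial instances an exact MAX-CUT solver (SDP/ILP)
  would be needed and is intentionally out of scope.
* The mean field is an approximation: on small dense graphs it reproduces
  the ordering and limits of the exact transition but not its exact shape,
  and no critical exponents are estimated.
* The $\delta_{max}$ bound and the sign-packing index are deliberately
  simple, documented constructions, and both are pluggable or
  replaceable; sharper alternatives exist in the signed-graph literature.
* GraphML/SBML input and database clients are out of scope; the readers
  cover plain-text edge lists and reaction tables.
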