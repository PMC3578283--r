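---
title: "Stability analysis of associative memory with dynamic synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability analysis of associative memory with dynamic synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpmem)
```

This vignette is the package's own account of the model it implements, the
numerical machinery behind the stability toolkit, and the design choices
that were genuinely open.

## The model and its assumptions

The network is a Hopfield-type associative memory of `N` stochastic binary
neurons with synchronous updates. A neuron fires with probability
`g(h) = (1 + tanh(h/T))/2` of its recurrent field; the noise intensity `T`
is the inverse gain of this response. Each synapse is dynamic in the
Tsodyks–Markram sense: a releasable resource `x` is consumed by
transmission (`−s x u` per step) and recovers toward 1 with time constant
`tau_R`; a utilization variable `u` jumps by `U_se (1 − u)` on each
presynaptic activation and relaxes toward the baseline `U_se` with time
constant `tau_F`. Transmission efficacy is the product `x u`, so the
synapse's effective drive is `2 s x u / U_se − 1`, normalized so that a
tonically silent synapse contributes −1 and a rested active one +1. The
update is a simultaneous map: all of `(s, x, u)` at `t+1` are computed from
values at `t`, and the depletion term of `x` uses the pre-facilitation
`u(t)`. That ordering is what makes the closed-form steady-state synapse
maps (below) the exact fixed points of the simulated dynamics.

Memories are `p` correlated ±1 patterns generated from a common parent:
each child entry copies the parent with probability `(1 + b)/2`. The
parent–child direction cosine concentrates at `b` and the child–child
cosine at `b²`. Couplings are Hebbian over the children only,
`J_ij = (1/N) Σ_μ ξ_i^μ ξ_j^μ` with `J_ii = 0`; the parent is exposed by
the generator but is not a stored memory. Fields are always evaluated
through the rank-`p` identity
`h = (1/N) Ξ (Ξᵀ σ) − (p/N) σ` (pattern-overlap accumulation with the
self-term subtracted), never through the dense `N × N` coupling matrix,
which at `N = 10⁴` would hold 10⁸ redundant entries of a rank-3 object.

## The sublattice reduction

Because `J_ij` depends on the neurons only through their pattern-bit
tuples, the set of neurons sharing a tuple `η ∈ {−1,1}^p` (a *sublattice*)
is dynamically homogeneous in the mean field. Taking noise averages,
assuming the usual `O(1/N)` factorization of `⟨s x u⟩`, and identifying
neurons within a sublattice yields a deterministic map on
`(m_η, X_η, U_η)` — `3·2^p = 24` variables at `p = 3` — with the field
`h_η = Σ_η' p_η' (η·η')(2 m X U/U_se − 1)`. The relative sizes `p_η`
default to their infinite-`N` values, `(1+3b²)/8` for `η = ±(1,1,1)` and
`(1−b²)/8` otherwise; `mf_spec(sizes = "empirical")` instead counts a
concrete pattern draw, which is the right choice when comparing against a
stochastic simulation of that same draw. The factorization assumption is
not proven for facilitating synapses; the package, like the analysis it
implements, validates it empirically by the agreement between stochastic
runs and the mean-field map (the test suite checks this at `N = 2000`,
where time-averaged retrieval overlaps agree to 0.05 away from stability
boundaries).

Two facts about this map shape the implementation:

* **The field is odd in `η`.** Since `p_η = p_{−η}` and
  `(−η)·η' = −(η·η')`, every state satisfies `h_{−η} = −h_η`, so after one
  step `m_η + m_{−η} = 1` identically. One consequence: the "activity
  inversion" `m'(η) = 1 − m(−η)` maps every fixed point to itself, so it
  cannot distinguish symmetric from symmetry-broken branches. The
  transformation that does is the pure relabeling `η → −η`
  (`state_negation()`), which sends a fixed point with overlaps `M` to one
  with `−M`; together with the `p!` pattern permutations it generates the
  six-fold orbit of a memory state.
* **Steady-state synapse maps are closed-form.** At constant activity `m`,
  `U = U_se(1 + tau_F m)/(1 + tau_F U_se m)` and `X = 1/(1 + tau_R U m)`.
  These provide consistent seeds (`state_from_m()`) and a residual check on
  every converged fixed point.

The microscopic mean-field map (one triple per neuron) is kept as a
validation bridge. With the self-coupling retained it reduces *exactly* to
the macroscopic map for sublattice-constant initial conditions — the suite
verifies 10³ steps at `N = 800` to 1e-10. With the network's `j ≠ i` field
the reduction is exact only up to `O(p/N)`, which is why the bridge exposes
an `exclude_self` switch.

## Fixed points, continuation, and bifurcation classification

Fixed points are solved by Newton iteration on the full 24-dimensional
`F(z) − z = 0` with the analytic Jacobian; the activity rows couple all
sublattices through `g'(h)`, the synapse rows are diagonal. (In assembling
the Jacobian, the cross-derivative of the activity map with respect to the
utilization is the `g'(h)·(2 m X/U_se)`-weighted block — the structural
analogue of its `X` counterpart; the utilization row itself never depends
on the resource.) Convergence tolerance is 1e-12 on the max-norm residual;
iterates are softly clipped to the admissible box and solutions outside it
are rejected rather than repaired. The seed family mirrors the state
classes: `m = 1/2` (PARA), `(1 ± c η^μ)/2` (six MEM seeds),
`(1 ± c·sgn(Ση))/2` (two SMIX), `(1 ± c·sgn(Ση − 2η^μ))/2` (six AMIX),
with `c = 0.8` and synapse variables from the steady-state maps.

Branches are continued in `T` by natural-parameter stepping (default
`ΔT = 5·10⁻³`) with a secant predictor, adaptive halving on failure, and a
branch-jump guard that rejects corrector solutions far from the predictor.
Step underflow below 1e-6 declares a fold. Unit-circle crossings of the
spectrum along a branch are refined by bisection (default 1e-4, so printed
three-decimal bifurcation values are decided), re-solving the fixed point
at each midpoint.

Classifying a *real* eigenvalue crossing +1 needs more than the spectrum,
and the discriminator here is geometric. Newton solves seeded off the
critical eigenvector on both sides of the refined crossing probe for
transversally intersecting fixed points:

* distinct fixed points on **both** sides: transcritical — the branch
  persists and exchanges stability with the intersecting family (this is
  what happens twice on the symmetric-mixture branch);
* a pair on **one** side only, carried by a negation-invariant trunk:
  pitchfork — the symmetry-broken pair merges into the trunk (the
  paramagnetic state stabilizes here);
* a pair on one side of a non-invariant branch: reported as saddle-node —
  a symmetry-related pair of off-branch fixed points annihilates at the
  crossing while the carrying branch persists (the asymmetric-mixture
  destabilization has this geometry);
* no transversal branch found: the crossing is reported as `"RC"`,
  unclassified, rather than guessed.

Complex-pair crossings of modulus 1 are Neimark–Sacker points, the
discrete-map Hopf analogue, and give birth to invariant circles.

## Oscillatory regimes: emergence versus existence

Oscillatory attractors are mapped by brute force with the compiled
macroscopic iterator. Two distinct questions get two distinct procedures,
and conflating them changes the answers by large margins:

* **Existence / supercritical collapse** (`oscillation_range()`): sweep a
  `T` grid with orbit inheritance, discard a 5·10³-step transient, measure
  overlap extrema and MED over a 10⁴-step window, declare oscillation above
  a peak-to-peak amplitude of 1e-3. Swept upward, the amplitude collapses
  smoothly at the supercritical Neimark–Sacker boundary, which this
  procedure localizes to the grid step. Swept downward it tracks the
  invariant circle as a coexisting attractor deep into the bistable region
  — in the facilitation regime the in-phase circle remains an attractor
  (verified through 10⁶ iterations) more than 0.1 below the noise level at
  which oscillations show up in simulations.
* **Emergence** (`oscillation_onset()`): at each `T`, a batch of
  trajectories starts from the random near-zero-overlap state that a
  simulation of the network itself would start from — `m = 1/2` plus
  Gaussian sublattice fluctuations of the finite-size scale
  (`σ ≈ 1/(2√(N p_η)) ≈ 0.015` at `N = 10⁴`), resting synapses `x = 1`,
  `u = U_se`. The onset is the lowest `T` from which any trajectory reaches
  the oscillation. This reachability notion is what "oscillatory states
  appear" means operationally in simulations started from unbiased
  activity, and it is the package's reported band onset. It is stochastic;
  the batch size (20) and scan step (0.001) put its run-to-run variation at
  a few thousandths in `T`.

The subcritical gap between the two notions is itself a result: in the
depression regime the emergence onset undercuts the fixed-point
Neimark–Sacker point, exposing the narrow window where stable retrieval
and the quasi-periodic orbit are multistable.

MED classification uses the per-step effective dimension at the tolerance
`ε = 1e-5`: ED = 1 when all three overlaps are pairwise closer than `ε`,
3 when all pairwise distinct, 2 otherwise, averaged over the measurement
window. For converged mean-field fixed points the classification
tolerances are 1e-6 (deterministic quantities); for time-averaged
stochastic traces a loose 0.05 is appropriate instead. Exact ties between
the memory and asymmetric-mixture signatures are labelled UNCLASSIFIED
rather than resolved by fiat.

## What the synthetic patterns do and do not emulate

The generator reproduces the correlated-memory ensemble: unbiased ±1
parent, children tied to it with correlation `b`, and the induced
sublattice-size profile. It does not model sparse/low-activity coding,
diluted or asymmetric connectivity, more than one correlation level, or
finite-size correlations between pattern draws and dynamics (patterns and
simulation noise use independently seeded RNG streams). Tests passing on
this ensemble therefore say nothing about, e.g., metastable retrieval in
sparsely coded networks.

## Numerical choices and problem sizes

Defaults chosen once and used throughout: Newton tolerance 1e-12 (residual
reported per fixed point); stability margin 1e-8 on the spectral radius,
with points inside the margin flagged marginal; continuation step 5e-3,
bisection refinement 1e-4; brute-force transient 5·10³, window 10⁴,
amplitude threshold 1e-3, onset batch 20 trajectories per 0.001 grid step.
The test suite exercises the stochastic network at `N ≤ 2000` and the
microscopic bridge at `N = 800`; the mean-field analyses are
`N`-independent. The acceptance script continues four branches per regime
sweep and runs in well under a minute on one CPU; phase-diagram grids are
the only genuinely expensive surface and default to coarse cells with
per-cell attractor searches.

## Known limitations

Only `p = 3` has closed-form sublattice sizes, an effective-dimension
classifier, and the full seed family; other `p` are supported by empirical
sizes but not by the state taxonomy. The deterministic limit `T → 0` is
excluded (minimum `T = 1e-6`); a sign-threshold response is provided
separately for exploration. Continuation is single-parameter; codimension-2
bifurcation curves in the phase diagrams are traced as stability-flag
boundaries on a grid, not continued directly. The branch-jump guard makes
branch hopping unlikely, not impossible, in regions dense with intersecting
unstable branches; downstream consumers should treat post-instability tails
of a branch as exploratory. Basin-dependent quantities (the emergence
onset) inherit the variance of their initial-condition ensemble.
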