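---
title: "Methods: the miR-200/ZEB switch, its landscapes, and delayed activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miR-200/ZEB switch, its landscapes, and delayed activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`emtdyn` studies a minimal two-variable model of the decision-making module
for epithelial--mesenchymal plasticity: the mutual inhibition between the
miR-200 microRNA family (`x2`) and the ZEB transcription-factor family
(`x1`), with ZEB self-activation. The upstream SNAIL signal is not modelled
mechanistically; its effect is folded into two lumped strengths, `a`
(activation of ZEB by signal and self) and `b` (inhibition of miR-200 by
signal and ZEB). The dimensionless equations are

$$\frac{dx_1}{dt} = \frac{a\,x_1^{n_1}}{\theta^{n_1}+x_1^{n_1}}
  + \frac{c\,\theta^{n_2}}{\theta^{n_2}+x_2^{n_2}} - k_1 x_1, \qquad
\frac{dx_2}{dt} = \frac{b\,\theta^{n_3}}{\theta^{n_3}+x_1^{n_3}} - k_2 x_2.$$

Two modelling commitments are baked in. First, the two production routes of
ZEB are *summed* ("and"-type simultaneous regulation), not multiplied.
Second, everything is dimensionless: concentrations are measured relative to
the common Hill threshold scale and time in units of the degradation time,
so the defaults `k1 = k2 = 1` and `theta = 0.5` fix the scales, the Hill
coefficients `n1 = 2, n2 = 6, n3 = 3` encode the relative number of binding
sites, and `c = 1` normalizes the miR-200 repression strength. These
defaults are the published circuit constants; all are user-settable, and all
reproductions in the test-suite pin them.

Phenotypes are read off stable fixed points with a threshold rule: **E**
(epithelial) when ZEB is off (`x1 < theta`), else **M** (mesenchymal) when
miR-200 is off (`x2 < theta`), else **HYBRID** (both intermediate — the
(1/2, 1/2)-type state). The rule is the natural dimensionless version of
"high miR-200/low ZEB", "low miR-200/high ZEB", "both intermediate"; it is
validated rather than assumed, by checking it reproduces the five-region
phase structure and the published pathway successions. The threshold is
configurable through `theta`.

# Deterministic analysis

**Scalar reduction.** The miR-200 equation is linear in `x2`, so its
nullcline is the explicit graph `x2*(x1) = b θ^{n3}/(k2(θ^{n3}+x1^{n3}))`.
Substituting into the ZEB equation turns the 2-D fixed-point problem into a
single scalar equation `g(x1) = 0` (`steady_residual()`). Because the two
production terms are bounded by `a + c`, all roots lie in
`(0, 1.5 (a+c)/k1]`; the solver brackets sign changes on a dense grid
(`1e5` points for a single parameter set, `2001` per point inside large
scans), polishes each bracket with 60 bisection steps plus a guarded Newton
iteration, and merges duplicates closer than `1e-6`. A column whose
sign-change count is even (generically impossible, since `g(0) >= 0 > g` at
the right end) is rescanned at tenfold resolution to recover root pairs
born near a fold. Stability comes from the analytic Jacobian; because the
off-diagonal product is non-negative the eigenvalues are real, and no
oscillatory attractors can arise in the undelayed model — the test-suite
asserts this rather than assuming it. Eigenvalues with real part within
`1e-8` of zero mark a near-bifurcation point: `classify_stability()` refuses
them unless the caller opts into a `"marginal"` label, and scan cells
containing one are labelled `"boundary"` and excluded from region counting.

**Phase diagram and pathways.** The default window `a ∈ [0, 2.5]`,
`b ∈ [0, 45]` at 250 × 250 contains the whole five-region structure and all
three published signal pathways; window and resolution are arguments, since
the printed diagram does not state its axis limits. SNAIL pathways are lines
`b = −α a + β` (a stronger signal raises `a` and lowers `b` when the SNAIL
pool is limited); `pathway_scan()` tracks every root along the line and
`regime_sequence()` collapses consecutive duplicate regimes. The published
blue pathway slope is taken literally as `α = 13.33` rather than 40/3; the
difference is far below scan resolution.

# Stochastic analysis

**Langevin convention.** Noise enters additively in both coordinates with
autocorrelation `2 D δ(t−s)` (homogeneous, `D1 = D2 = D`), so the
Euler--Maruyama increment is `sqrt(2 D dt) z` per coordinate. Concentrations
are kept non-negative by reflection at 0, matching the zero-flux boundary of
the Fokker--Planck solve; the model says nothing about the boundary, and
reflection is the choice that preserves normalization. The default step
`dt = 0.005` (cap `0.01`) was verified by halved-step comparison at the
noise levels used; trajectories escaping ten times the invariant box abort
with advice to reduce `dt`. All steppers run from R's RNG, so a seed fixes
every trajectory bit-for-bit.

**Stationary distributions.** Two routes are provided and cross-checked.
The Monte Carlo route pools every post-burn-in step of an ensemble (default
50 chains × 5000 time units, burn-in 500, chains started cycling over the
deterministic attractors so each basin is represented at small `D`). The
Fokker--Planck route discretizes the stationary equation by finite volumes
with Scharfetter--Gummel (exponential-fitting) face fluxes — positivity-
preserving and exact for locally linear drift — on a default 200 × 200 grid
with no-flux boundaries, and solves for the kernel of the conservative
discrete generator with one row replaced by the normalization constraint
(sparse LU via Matrix). The two routes agree to total-variation distance
below 0.05 at the tristable reference point at `D = 0.01`.

An honest caveat: ensemble Monte Carlo equilibrates *within* basins quickly
but equilibrates the *weights between* basins only when trajectories
actually cross. At the bistable point `(a, b) = (0.1, 1)` and `D = 0.01`
both escape barriers are near 8 in `U` units, passages essentially never
happen on any feasible horizon, and the Monte Carlo weights remain at the
start allocation; cross-method agreement there is only meaningful at mixing
noise (the suite checks it at `D = 0.05`). At `(1.1, 8)` the epithelial and
hybrid wells drain into M fast enough that the comparison at `D = 0.01` is
fair.

**Landscapes and barriers.** The potential is `U = −ln Pst`, clipped below
a probability floor (default: smallest positive mass / 10) so empty bins
stay finite. Attractors are grid minima of `U` (8-neighbourhood); the saddle
level between two minima is computed exactly in the minimax sense by a
sorted sweep with union-find — the lowest level at which the two basins
connect on the grid graph — and the barrier is `φ_SA = U(S) − U(A)`. When
reference attractors are supplied, each is matched to its nearest grid
minimum; `barrier_scan()` uses a match radius of 1.0 because shallow minima
drift along their valley as noise grows (the hybrid minimum moves visibly
with `D`, in both the Fokker--Planck and Monte Carlo landscapes — a genuine
noise-induced shift, not an artifact).

**Plateau rule.** The hybrid barrier decreases with `D` and then levels
off. The onset is defined as the smallest scanned `D` beyond which every
successive decrement falls below a declared tolerance; the default
tolerance is scale-free — one tenth of the largest decrement observed over
the scan — because the height scale of the published curve is not printed.
A well that has vanished from the landscape has stopped decreasing, so
missing values at the top of the scan count as zero decrements. On the
scanned grid `{0.01, 0.015, 0.02, 0.025, 0.03, 0.04, 0.05}` at 200 × 200
the rule places the onset at 0.04, one grid step above the published
critical value 0.03; the hybrid well itself survives to `D = 0.04` and is
washed out of the exact stationary landscape by `D = 0.05`.

**First-passage times.** `mfpt()` starts trajectories at the source
attractor and stops on entry into a capture ball (default radius 0.15)
around the target; the radius is always reported, since "reaching" a state
has no canonical definition. The classical 1-D double-integral formula is
provided as `mfpt_quadrature()` for one-dimensional reductions only — the
model itself is 2-D and the package makes no claim that a particular 1-D
reduction reproduces the 2-D passage times; all 2-D statements are made by
direct simulation. The formula's inner integral is accumulated from the
reflecting boundary (the lower end of the support) toward `y`; that
orientation is validated against direct simulation of a decoupled 1-D
instance (`b = c = 0`, pure ZEB self-activation) rather than trusted.

# Delayed self-activation

The delay `τ` enters only the ZEB self-activation term, which is evaluated
at `x1(t − τ)` from a ring buffer; `τ` is rounded to a whole number of
steps, and the pre-history is constant at the initial state — the minimal
choice, which makes the `τ = 0` limit exact. "Starting in state X" means
starting *at* the deterministic attractor of phenotype X. Two consequences
are worth stating plainly:

- Without noise, a delayed system started exactly at an attractor with
  constant history is still at equilibrium, so deterministic delay scans
  from an attractor are invariant in `τ` — the outcome depends only on the
  initial state, as the undelayed bistable scans also show.
- The delay's effect therefore expresses itself through fluctuations. The
  delayed positive self-feedback weakens the effective restoring force
  around any attractor whose self-activation slope is appreciable (the
  hybrid, and weakly M), inflating fluctuations there, while the epithelial
  state — whose activation slope vanishes at `x1 ≈ 0` for `n1 = 2` — is
  untouched. Noise alone preferentially drives E → M (the E-side barrier is
  lower); delay preferentially destabilizes the high-ZEB side. The two
  effects are opposite, and the suite demonstrates the competition at
  `(1.1, 8)` from the hybrid start: noise at zero delay drives the late
  ZEB level up toward M, and adding delay under the same noise pulls it
  back down.

`classify_trajectory()` reduces a trajectory to a final label (late-window
mean state mapped to the nearest attractor within the capture radius, else
`UNSETTLED`), sustained- and transient-oscillation flags (half peak-to-peak
amplitude of `x1` against `osc_tol`, default 0.1), and a dwell-filtered
sequence of visited phenotypes (dwell ≥ 20 time units). `tau_scan()` runs
`n_reps` seeded replicates per delay (20 by default under noise) and
reports full label counts plus the majority label, so stricter decision
rules can be applied downstream. The published delay figures do not print
their `τ` or `D` values; the default scan `τ ∈ {0, 0.5, 1, 2, 5, 10, 20}`
and `D = 0.01` (the noise level used elsewhere) are choices, and the
delay-scan demonstrations assert directions of effect, not specific
thresholds. At the bistable point `(0.1, 1)` the self-activation slope at M
is so small (≈ 0.03) that a delay-induced majority flip M → E does not
appear at these defaults — the late ZEB level falls with `τ` only at
mixing noise levels; only the direction of the effect is claimed there.

# Problem sizes and reproducibility

The suite and the acceptance script use: 250 × 250 phase-diagram cells
(2001-point root bracketing per cell), 300-point pathway scans, 200 × 200
Fokker--Planck grids over seven noise intensities, Monte Carlo ensembles of
50 × 5000 time units at `dt = 0.005`, and 500 first-passage trajectories
per condition at `dt = 0.01`. Every stochastic quantity is seeded; a single
run seed is expanded into per-component streams with a counter scheme
(`split_seed()`), so adding an analysis never perturbs existing streams,
and CLI runs rewrite byte-identical artifacts from their recorded
configuration.

# Known limitations

- The four-component SNAIL/miR-34/miR-200/ZEB network is out of scope; the
  SNAIL arm exists only through `(a, b)` and the pathway lines.
- The landscapes and barriers are *finite-noise* constructions from
  `U = −ln Pst`; they are not the zero-noise quasipotential, and barrier
  values depend (weakly, and convergently under refinement) on the grid.
- Ensemble Monte Carlo weights between non-mixing basins reflect the start
  allocation, as discussed above.
- The 1-D first-passage quadrature applies to 1-D reductions only.
- Simulated noise is additive, white and homogeneous; real transcriptional
  noise is neither, so quantitative switching times should be read as
  model statements, not cell-biological predictions.
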