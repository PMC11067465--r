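---
title: "Schooling models and force-map inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schooling models and force-map inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`schoolforces` simulates a two-dimensional school of N self-propelled
individuals (unit mass, so forces and accelerations share units cm/s²).
Each individual i feels

* a **social force**, averaged over its interacting set with
  inverse-distance weights,
  composed of a pairwise attraction–repulsion spring
  `F_ij = -k (d_ij - d0) (x_i - x_j)/d_ij`
  (with `k = k_rep` at or below the equilibrium distance `d0` and
  `k = k_att` above it) and a pairwise alignment force
  `F_ij = -mu (v_i - v_j)` that pulls the full velocity vector — speed
  *and* heading — toward the neighbor's;
* a **friction–propulsion force** `-( |v_i| - v0 ) / tau_v * vhat_i`
  relaxing the speed to the preferred speed `v0` on the timescale
  `tau_v`; and
* **active noise** `sigma_v xi_v vhat_i + sigma_phi xi_phi phihat_i`
  with independent unit Gaussians along and perpendicular to the heading.

The interacting set is the Voronoi neighborhood (individuals whose
Voronoi cells share an edge — a standard proxy for visual interaction
networks), recomputed every step. Variants of the interaction rule:

* `standard` — all Voronoi neighbors;
* `selective` — only Voronoi neighbors moving *strictly faster* than the
  focal individual (a speed tie counts as not faster; ties have measure
  zero). An individual whose neighbors are all slower feels no social
  force at that step;
* `antialign` — the pairwise alignment term is replaced by a tabulated
  2-D force field evaluated at the relative velocity with the nearest
  neighbor in the focal frame (see *Force maps* below); attraction–
  repulsion is unchanged;
* `persistent` — standard interactions, but each individual switches
  with probability rate `r` into a "private" state in which social
  forces are off and a force of amplitude `A` acts in a fixed random
  direction for `tau_p` seconds;
* `nearest` — nearest neighbor only, with weight 1 (a testing aid).

### Reference parameters

The defaults of `school_params()` are the reference set used throughout:

| parameter | value | units | meaning |
|---|---|---|---|
| `k_rep` | 12.5 | s⁻² | repulsive spring constant |
| `k_att` | 5 | s⁻² | attractive spring constant |
| `d0` | 5.8 | cm | equilibrium distance |
| `mu` | 1.5 | s⁻¹ | alignment constant |
| `v0` | 11 | cm/s | preferred speed |
| `tau_v` | 1.6 | s | speed relaxation time |
| `sigma_v` | 6.4 | cm s^-3/2 | noise along the heading |
| `sigma_phi` | 2.6 | cm s^-3/2 | noise perpendicular to the heading |
| `dt` | 0.02 | s | integration step |
| `n_individuals` | 39 | — | school size |

### Integration

The stochastic equations of motion are integrated with the
Euler–Maruyama scheme: `v <- v + F_det dt + noise sqrt(dt)`, then
`x <- x + v_new dt` (semi-implicit ordering — the position uses the
updated velocity; the ordering matters at O(dt) and is fixed for
determinism). The `sqrt(dt)` convention matches the noise units
cm s^-3/2. Recorded accelerations are the deterministic force plus the
realized noise increment divided by dt — i.e. exactly what
differentiating the trajectory would give, which is what force-map
inference consumes.

Headings are taken from the current velocity; if a speed ever falls
below 1e-9 cm/s the step stops with a degenerate-state error rather
than guessing a heading (with `v0 = 11` and the reference noise this is
unreachable in practice). The simulation plane is unbounded.

### Initial conditions and transient

Positions are drawn uniformly in a disc whose radius targets a mean
nearest-neighbor distance of `d0` (for a Poisson process of density rho
the mean nearest-neighbor distance is `0.5/sqrt(rho)`); speeds start at
`v0` with uniformly random headings. The first `n_transient` frames
(1,000 by default) are discarded.

### Weight normalization

The inverse-distance weights admit three readings, exposed as
`weight_norm`:

* `"set"` (default): weights normalized over the interacting set — a
  weighted *average*, so a single neighbor always has weight 1 and the
  force scale is decoupled from the local density;
* `"voronoi"`: weights normalized by the sum of `1/d` over *all* Voronoi
  neighbors but summed over the interacting subset — under the selective
  rule, ignoring a neighbor then genuinely reduces the total social
  input;
* `"none"`: the raw `1/d`-weighted sum.

The three coincide for the standard variant up to the local value of
`sum(1/d)` (about 1 at the reference density) and differ for the
selective variant. We simulated all three; the qualitative signatures
discussed below are the same, and `"set"` is the default.

## Force maps

A force map estimates an effective force as the binned mean of
individual accelerations against a chosen relative coordinate, on the
assumption that all other force terms average out. Coordinates are
expressed in the **focal frame** (y-axis along the focal individual's
motion, x-axis to its right):

* *relative position* `x_i - x_NN` (attraction–repulsion map, grid
  ±20 cm by default);
* *relative velocity* `v_i - v_NN` (alignment map, grid ±15 cm/s).

Both use the nearest neighbor by default (`neighbor = "voronoi"` emits
one sample per Voronoi pair instead). Grids are 30×30 and bins with
fewer than `min_count = 50` samples are masked; these are deliberate
defaults chosen to resolve structure at the reference scales, not
reconstructions of any published binning. The **radial projection**
(dot product of the bin mean with the unit vector from the origin) reads
the maps at a glance: negative is inward — attraction, alignment —
positive is outward — repulsion, antialignment. `radial_force_profile()`
averages the radial component in 1-D distance bins;
`profile_zero_crossing()` locates the repulsion-to-attraction sign
change, which for the standard model sits at the equilibrium distance.

Conditional sample filters (`sample_filter()`) reproduce the robustness
checks used on experimental recordings: nearest-neighbor distance range,
wall distance (takes explicit tank geometry — simulations are
unbounded), approach/recede (`sign of d(d_ij)/dt`), relative-heading
range, focal-speed range, and the neighbor faster/slower split.

For the `antialign` variant, `smooth_and_interpolate_field()` turns a
binned map into a continuous driving field: masked bins are filled from
their nearest valid neighbors *before* smoothing (so the Gaussian filter
never bleeds mask sentinels), each component is smoothed with a
sigma = 2 bin Gaussian, and lookups interpolate bilinearly with the
boundary value clamped outside the grid.

## Two kinematic conventions, and why they matter

An ensemble carries one of two kinematic conventions, never mixed:

1. **Integrator kinematics** — velocities and accelerations as recorded
   by the simulator.
2. **Tracked kinematics** (`tracked_kinematics()`,
   `smooth_and_differentiate()`) — positions smoothed by a Gaussian
   kernel (sigma = 2 frames, truncated at 5 sigma), velocities and
   accelerations from the first and second Gaussian-derivative kernels.
   This is the standard estimator for video-tracked recordings; applying
   it to simulation output analyzes the model exactly as experimental
   data are analyzed.

The choice is not cosmetic, and the package takes a deliberate position:

* On integrator kinematics the binned-mean estimator is *consistent*
  for the model's forces: per-step noise is independent of the current
  state, so it averages out of every bin. The standard model's
  alignment map is inward in every populated bin and the
  attraction–repulsion profile crosses zero at `d0` — this convention
  is used when the question is "does inference recover the generating
  forces?".
* On tracked kinematics the smoothed coordinate at time t contains
  noise increments that also enter the smoothed acceleration at t. For
  a stationary state driven by white noise this correlation *exactly
  cancels* the linear restoring signal in the covariance
  (`cov(smoothed state, d/dt smoothed state) = 0` by stationarity), so
  the standard model's alignment map loses most of its inward signal.
  What survives are slower, systematic correlations — and that is
  precisely what the selective-attention and leadership signatures are:
  * In the **selective** model the focal individual ignores a slower
    nearest neighbor, and its acceleration is instead driven by
    attraction to farther, faster neighbors at effectively random
    relative directions. On tracked kinematics this appears as an
    outward (antialignment) radial component in the neighbor-slower
    half of the alignment map, with the neighbor-faster half inward —
    about 73% of populated upper-half bins outward and over 90% of
    lower-half bins inward in the reference runs.
  * The **surrogate self-delay maps** (individual at t paired with
    itself at t ± 0.2 s) are fully inward for positive delay (a
    follower aligns with its leader) and fully outward for negative
    delay on tracked kinematics; on integrator kinematics the
    negative-delay side largely vanishes because the white-noise part
    of the recorded acceleration is uncorrelated with the past.

  A second, purely dynamical effect compounds this: under the selective
  rule alignment only ever pulls speeds *up* toward faster neighbors,
  so the stationary mean speed rises well above `v0` (about 19 cm/s at
  reference parameters) until friction balances the one-sided pull. On
  integrator kinematics the friction term then leaks a strong inward
  component into the neighbor-slower half (being faster than the
  neighbor correlates with being above `v0`) and masks the
  antialignment signature entirely.

The acceptance analyses therefore use integrator kinematics for the
standard-model closure checks and tracked kinematics for the
selective-signature and surrogate-duality checks, mirroring how each
question is posed against data. Users comparing either map against
video-tracked recordings should always use `tracked_kinematics()` on
the simulation side.

## Observables

`observables_summary()` collects the comparison measures: polarization
(modulus of the mean heading unit vector), instantaneous mean
nearest-neighbor distance, convex-hull area per individual, Voronoi
contact durations (maximal runs of pair adjacency; strictly contiguous
by default, with an optional gap tolerance defaulting to 0 since no
principled gap length exists), individual speeds, and signed turning
rates `(vx ay - vy ax)/|v|^2` (the cross-product form avoids 2-pi wrap
artifacts of differencing heading angles). `pdf_with_error_band()` bins
any of these with a Bernoulli-standard-deviation error band,
`sqrt(p(1-p)/n)` per bin, divided by the bin width.

On matched reference runs the selective school is, relative to the
standard one: less polarized, more variable in nearest-neighbor
distance and in speed, more extended per capita, and faster at
reshuffling neighbors (shorter median contact durations) — the
qualitative ordering the model comparison relies on, asserted by the
test suite.

## Leadership

`delayed_correlations()` pools, for each signed delay tau, all (focal,
frame) samples passing a state filter at the reference time t and pairs
the focal individual with its *time-t* nearest neighbor evaluated at
t + tau (identity tracked, not re-evaluated; edge frames are dropped).
It reports the mean heading dot product and the Pearson correlation of
speeds, each with its curve maximum. State filters: `faster`/`slower`
(strict speed comparison with the nearest neighbor) and
`frontal`/`rear` (sign of the neighbor-relative position along the
focal heading). On selective-model runs the faster-filtered orientation
curve peaks at strictly positive delay and the slower-filtered one at
strictly negative delay — faster individuals lead, slower ones follow.
The faster and slower curves need not mirror each other because
nearest-neighbor relations are not reciprocal; no symmetry is asserted.
The copy-with-lag fixture (`fixture_copy_lag()`), where one individual
reproduces the other's velocity after a known number of frames, pins the
peak location exactly and anchors the sign conventions.

## Synthetic data: what it emulates and what it does not

The simulator *is* the data generator for all tests: there is no bundled
experimental data. It emulates stationary free schooling of a mid-size
group in open water at a fixed frame rate — group sizes, speeds and
length scales follow the reference parameter table. It does not emulate
tank walls (no boundary forces), burst-and-coast locomotion (speed
oscillations arise only from noise plus relaxation), body shape,
hydrodynamics, or tracking artifacts such as identity swaps and
occlusions (`interpolate_gaps()` exists for real data but fixtures are
gap-free). Passing tests therefore demonstrate internal consistency of
simulation, inference and leadership analysis under the model's own
assumptions — not that the model captures any particular real school.

## Numerical choices

* **Voronoi adjacency** is computed by a brute-force empty-circumcircle
  test with early exit (N is tens, recomputed every step in C++). Exact
  cocircular ties — e.g. a perfect square — are broken by a
  deterministic index-dependent jitter of 1e-9 times the coordinate
  scale, applied only inside the adjacency test. Duplicate or fully
  collinear configurations raise errors; fewer than three individuals
  fall back to all-pairs adjacency.
* **Closed-form recoveries** of `tau_v` and `mu` from simulated decays
  invert the integrator's exact one-step contraction
  (`mu_hat = (1 - exp(-lambda dt))/(2 dt)` from the fitted log-slope
  `lambda`) rather than reporting the raw slope, which is biased by
  `-log(1 - 2 mu dt)/(2 mu dt)` (about +3% at the reference step).
* **Boundary handling** for Gaussian filtering is reflection padding;
  the first and last `5 sigma` frames are flagged (and dropped by
  `tracked_kinematics()`).
* **Gap filling** uses cubic splines on the valid frames, fills gaps up
  to `max_gap = 10` frames (0.2 s) and leaves longer or boundary gaps
  masked.
* **Perspective correction** solves the 8-parameter homography mapping
  the four imaged tank corners to a physical square exactly.
* Problem sizes: ensemble-level checks use N = 39 with 30,000
  post-transient frames (the scale at which the map signatures are
  stable); unit-level checks use N ≈ 10–12 with a few thousand frames.

## Known limitations

* The force-map method is a binned regression; inferred rules are not
  unique, and the two-convention discussion above is itself an example
  of estimator-dependence that any force-map study should confront.
* The selective variant's elevated stationary mean speed is a real
  property of the rule as specified, not a bug; applications that need
  speeds pinned near `v0` must modify the propulsion term, which the
  package deliberately does not do.
* The brute-force Delaunay test is O(N³)-ish per frame and comfortable
  up to a few hundred individuals; larger groups would want a proper
  incremental triangulation.
* Delay grids are restricted to integer multiples of the frame spacing;
  no temporal interpolation is performed anywhere.
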