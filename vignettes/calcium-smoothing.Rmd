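---
title: "Spatiotemporal MAP smoothing of dendritic calcium signals: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal MAP smoothing of dendritic calcium signals: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dendrosmooth)
```

## The estimation problem

Random-access multi-photon microscopy samples fluorescence at a sparse,
user-chosen set of points on a dendritic tree, thousands of times per
second.  A high-affinity calcium indicator (e.g. Oregon Green BAPTA-1)
binds calcium effectively instantaneously and unbinds slowly, so each
fast depolarization — a backpropagating action potential (bAP) or a
synaptic potential — appears as a jump in bound-indicator concentration
followed by an exponential decay with the unbinding time constant `tau`.
Fluorescence is affine in bound-indicator concentration, and after
dF/F normalization, `(F - F_b)/F_b`, the normalized trace is
proportional to the relative concentration change with a single global
gain.  The concentration is therefore identified only up to an affine
transformation; everything this package estimates is on that relative
scale, which preserves transient timing and relative amplitude — the
quantities of scientific interest.

## Model

**Spatial expansion.**  The relative concentration over the `N`
compartments is written `c_t = B a_t`, where the columns of the `N x d`
matrix `B` are nonnegative bump functions of the topological distance
along the tree (not through space) from `d` center compartments.
Centers are placed greedily from the root so that consecutive centers on
any root-to-leaf path are `spacing` hops apart; the soma is always a
center.  The default bump is the cubic B-spline kernel of the scaled hop
distance `h / spacing`, truncated at `2 * spacing` hops (its natural
support), and a Gaussian bump is available behind `form = "gaussian"` —
the reconstruction is insensitive to the exact shape as long as the
bumps are smooth and roughly uniform.  Two choices here were genuinely
open:

* *Branch points.*  A bump whose subdomain reaches a branch point
  spreads down every daughter branch; its subdomain is simply the set of
  compartments within the hop radius, whichever branch they lie on.
  When two centers' subdomains overlap asymmetrically at a branch point
  we let both bumps keep their full truncated support rather than
  partitioning it.
* *Normalization.*  Columns are peak-normalized to 1 rather than forming
  a partition of unity, so a prior amplitude `A_i` on state `i` maps
  directly onto a transient height of `A_i` (in dF/F units) at the
  center compartment.

**Dynamics.**  The weights decay as `a_t = alpha a_{t-1} + u_t` with
`alpha = 1 - delta/tau` and nonnegative innovations `u_t`.  We define
the resting state as `a_0 = 0` (zero *relative* concentration), so the
prior on the initial value is simply the prior on `u_1`.  Note that
`u >= 0` together with `a_0 = 0` and `alpha` in `(0, 1)` implies
`a >= 0` by induction, so only the innovations need to be constrained.

**Measurements.**  Each bin images `n_t` compartments (possibly zero;
`n_t` may change freely over time).  The inference likelihood is
Gaussian with per-site standard deviation `sigma_x` on the normalized
data.  Photomultiplier (PMT) output is modelled generatively as
`y ~ Gamma(shape = slope * I, scale)`: mean proportional to the true
intensity `I`, skewness `2/sqrt(slope * I)` — exponential-like at low
light, near-Gaussian at high light.  The shape-linear-in-intensity,
fixed-scale parameterization is this package's choice; it keeps the
log-likelihood concave in the latent intensity (the shape enters through
`-log Gamma`, which is convex), so the same interior-point machinery
applies when the exact gamma likelihood is requested
(`likelihood = "gamma"` on raw intensities).  The default, mirroring
common practice on real recordings, is the Gaussian likelihood on dF/F
data even when the data were generated with PMT noise.

**Prior.**  Innovations are independent exponentials with mean
`A_i * delta * r(t)`: a log-concave surrogate for a marked point process
with rate `r` and mean mark `A_i`.  The negative log-posterior is then

```
sum_t ||y_t - M_t (gain * B a_t)||^2 / (2 sigma^2)
  + sum_t lambda_t' u_t,       lambda_t[i] = 1 / (A_i * delta * r_t),
```

minimized subject to `u_t >= 0`.  The rate schedule `r(t)` is low before
stimulation, `r_high = 10 /s` inside the stimulation window (ten evoked
spikes per one-second window is the motivating protocol), and relaxes
*continuously* afterwards as
`r_low + (r_high - r_low) exp(-(t - t_off)/decay_tau)`.  The exact decay
form was open; we chose exponential relaxation because any discontinuity
at the window end makes the prior infer a spurious event there, and an
exponential is the simplest continuous interpolant with a controllable
time scale (default `decay_tau = 0.2 s`).  `r_low` must stay positive so
prior mass never vanishes (default `0.01 /s`).

## Optimization

The constraints are handled by a log-barrier interior-point method over
the weight trajectory `a` (length `T * d`):

* **Feasible start** — `u` constant at 5% of the mean prior amplitude
  (floor `1e-4`).
* **Barrier schedule** — initial weight chosen so the barrier term is
  roughly 10% of the initial objective; geometric growth by `x10`;
  termination when the suboptimality bound `T*d / weight` drops below
  `gap_tol` (default `1e-6`), with the final weight capped at
  `1.01 * T*d / gap_tol` so the last stage is not needlessly extreme.
* **Newton** — each stage is solved by damped Newton with backtracking
  (Armijo) line search, the step capped at 0.99 of the distance to the
  feasible boundary.  A stage stops when half the squared Newton
  decrement falls below `newton_tol * max(1, |phi|)` (default
  `newton_tol = 1e-8`) or the objective improves by less than `1e-10`
  relative — both scale-invariant.
* **Structure** — the barrier contributes `diag(1/u_t^2)` curvature
  coupling only adjacent bins, and the data term couples states within a
  bin, so the Hessian is block-tridiagonal with diagonal off-blocks.
  The Newton direction is computed by block-Thomas forward elimination /
  back substitution with a dense Cholesky per `d x d` block: time and
  memory linear in `T`.  Two numerical safeguards matter near the
  boundary: `1/u` is evaluated with `u` floored at `1e-14` (anything
  smaller is numerically an active constraint), and a block whose Schur
  complement loses positive definiteness to rounding is retried with an
  escalating vanishing jitter before an error is raised — a genuinely
  indefinite block still errors with its time index, which signals a
  line-search bug rather than a data problem.

`map_reference_dense()` solves the same objective with `optim`'s
L-BFGS-B over the innovation vector under box constraints — a generic
solver that shares no code with the structured path — and the test suite
requires objective agreement to `1e-6` relative on randomized instances.

## Parameter estimation

All parameters are estimated from the data, in this order:

| quantity | method | default knobs |
|---|---|---|
| baseline `F_b` | per-site mean of raw values in the quiet pre-window | `t_pre = 0.4 s` |
| decay `alpha`, `tau` | pooled AR(1) on filtered, baseline-subtracted traces after the last evoked event: `alpha = sum z_t z_{t-1} / sum z_{t-1}^2` | filter width `0.05 s` |
| transient amplitudes | max increase of the filtered dF/F trace after the first bAP relative to just before it, floored at 0 | window `0.1 s` |
| spline spacing + `A_i` | decrement spacing from `s_init` until the NNLS fit `min_{lambda>=0} ||B_sites lambda - amp||` has relative error <= `tol` | `tol = 0.1`, `s_init = 8` |
| noise `sigma_x` | sd of residuals (data minus filtered trace), mean fixed at 0 | quiet window, attenuation-corrected |

Notes on the open or refined choices:

* The AR(1) fit pools all sites into a single `alpha` (per-group fitting
  is available via the `groups` argument); on real recordings subtree
  estimates tend to agree.
* The relative error in the spacing search is the Euclidean norm over
  imaged sites.  The spacing search operates in hops, matching the
  "number of compartments" reading of center spacing; physical-distance
  topological distances are used everywhere else (a `hops` flag is
  available).  The search error is *not* monotone in the spacing —
  bases at different spacings are not nested, so adding states can
  transiently fit worse — and the selection rule never relies on
  monotonicity: it simply stops at the largest spacing meeting the
  tolerance (or spacing 1, which interpolates).
* Degenerate NNLS designs are resolved toward the minimum-norm solution
  by a vanishing ridge.
* Raw residual standard deviations are biased: down by
  `sqrt((w-1)/w)` because a width-`w` moving average partially
  reproduces the noise it is subtracted from, and up near transients
  where the filter lags the signal.  `estimate_noise_sd()` therefore
  estimates on the quiet pre-stimulation window when it is populated and
  applies the exact `sqrt(w/(w-1))` correction.  When sampling is so
  sparse that every observation is isolated in its window (all residuals
  zero, as under heavy temporal subsampling), the pipeline widens the
  noise-estimation window until residuals become informative.
* Prior amplitudes that the NNLS sets exactly to zero are floored at
  `1e-3` of the largest, since a zero amplitude makes the exponential
  prior degenerate.

## Tree handling

SWC morphologies are read with arbitrary ids mapped to contiguous
indices in file order; every SWC point is a compartment (no resampling).
Before analysis the tree is pruned to the branches that carry data: a
compartment survives iff its subtree contains an imaged site.  This
keep-rule is a package choice — side branches *between* imaged sites are
removed unless they themselves contain a site — because the prior would
shrink their field toward zero anyway, and removing them makes the state
space honest about what the data can constrain.  Pruning is idempotent
and returns an injective old-to-new index map.

## The synthetic-experiment generator

`simulate_experiment()` emulates the motivating bench protocol: a train
of bAPs at specified times sweeps the tree instantaneously and
unselectively, with per-state amplitude `A0 * exp(-dist_i / L)` decaying
with the topological distance of the state's center from the soma;
optional EPSPs add amplitude only to states whose centers lie within a
hop radius of the stimulated compartment; each bin images a uniform
random subset of compartments without replacement; noise is Gaussian or
gamma-PMT.  Selective bAP failure can be emulated with per-state
amplitude masks (deterministic event lists).  The generator reproduces
the features the smoother exploits — sparse nonnegative innovations,
AR(1) decay, distance-decaying amplitude, random-access scanning,
intensity-dependent noise — and deliberately omits what the model also
omits: voltage biophysics and propagation delays, calcium diffusion
between compartments, dye saturation, and slow baseline drift.  Passing
tests on synthetic data therefore demonstrate correct inference *under
the model's own assumptions*, plus robustness to the gamma/Gaussian
likelihood mismatch; they do not certify behaviour under saturation or
nonstationary baselines, which real recordings do show.

Generator defaults used across the test suite are chosen once as
realistic for OGB-1-class indicators and PMT detection: `delta = 10 ms`,
`tau = 0.2 s`, somatic transient amplitude of order 1 dF/F with length
constant about half the tree depth, baseline intensities of 100–400
(giving dF/F noise of 5–10%), and PMT gamma shape equal to the intensity
(`slope = 1`), for which skewness at baseline is `2/sqrt(F_b)`.

## Problem sizes and behavioural checks

The test suite exercises, among others: exact recovery of three bAPs at
bins 20, 50 and 66 on a 200-compartment tree with 27 states and 100 bins
under gamma PMT noise; solver equivalence with the dense reference on
20 randomized instances (50 bins, ~8 states, 30 compartments);
linearity of the Newton-direction cost over 250–2000 bins at 20 states;
median recovery of `alpha` / baseline / `sigma` over 100 simulated
recordings of 1000 bins; prior-induced amplitude shrinkage over 50
replicates; leave-site-out cross-validation (interior sites are
interpolated with preserved event times, unimaged branch tips shrink
toward zero); and 4x temporal subsampling (field correlation with the
full-data fit above 0.8).  These sizes were chosen as the smallest that
exercise each property cleanly.

## Limitations

* Innovations are independent across states and time; synchrony along
  the tree (group-sparse priors), spatially coupled innovation dynamics,
  and a decreasing-amplitude constraint along the tree are natural
  extensions not implemented here.
* The baseline is constant in time; slow drift shows up as small
  spurious events after the stimulation window.
* Amplitude estimates are biased downward by the exponential prior (the
  robustness/bias trade-off is intentional); `known_times_mle()` offers
  the unshrunk constrained MLE when event times are known.
* The per-block Cholesky in the Newton solve is dense, so cost grows
  cubically in the number of states per block; with the state counts the
  spacing search selects in practice (tens), the time dimension
  dominates and the fit is effectively linear in the experiment length.
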