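---
title: "Scale-free chaos in the harmonically confined Vicsek model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-free chaos in the harmonically confined Vicsek model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`swarmchaos` simulates `N` self-propelled particles in the plane moving at a
fixed dimensionless speed `v0`. At every discrete time step each particle
aligns with the particles inside a metric radius `r0` (strict inequality,
itself always included) while a linear spring `-beta * x` pulls it toward the
origin — the harmonic trap plays the role that periodic boundaries play in
the classical Vicsek model, and mimics the marker fixation of natural midge
swarms. The synchronous update is

    F_i     = sum_{j : |x_j - x_i| < r0} v_j(t) - beta * x_i(t)
    v_i(t+1) = v0 * R(xi_i) F_i / |F_i|,   xi_i ~ U[-eta/2, eta/2]
    x_i(t+1) = x_i(t) + v_i(t+1)

where `R(xi)` is a rotation by the angular noise `xi`. Units: one time step
is the observational sampling interval, one length unit is the mean
nearest-neighbor distance, so `v0 = v * dt / r1` ([`nondimensionalize()`]);
the observed midge constants (`v = 0.195` m/s, `dt = 0.24` s, `r1 = 4.68`
cm) give `v0 = 1`, the package default, together with `r0 = 0.472`.

Particles start uniformly in the unit disc with outward headings
(`init_swarm()`).

### The force convention

The discrete rule is printed ambiguously in the literature of this model:
the confinement term can be read inside or outside the neighbor sum.
`swarmchaos` defaults to `focal_once` (`F_i = sum_j v_j - beta x_i`):
the linearized dynamics of the model carries a single `-beta dx_i` term per
particle, and a harmonic potential acts on each particle once. The
`per_neighbor` variant (`F_i = sum_j (v_j - beta x_j)`) is retained behind
`hcvm_params(force_convention=)` for sensitivity analysis. This choice
matters quantitatively at strong confinement: with `N = 128`,
`beta ~ 100`, `eta = 0.5` the tangent-space Lyapunov exponent is about
0.20/step under `focal_once` and 0.09/step under `per_neighbor`, while both
conventions agree in the weak-confinement regime (`beta` below ~1e-2
at these sizes) where the scale-free analysis happens — there the spring
term is a small perturbation of the alignment sum. Published simulations of
this family of models report substantially weaker tangent-space growth at
strong confinement than either convention produces here; we verified our
tangent map against a finite-difference oracle of the full update and
against two-clone shadow trajectories with shared noise, so the values this
package computes are faithful to the update rule as written above. Results
at `beta >> 1` should therefore be read as properties of this exact rule,
not of any particular published variant.

Other conventions fixed here (all measure-zero or paired with the model):
noise is applied as a rotation after normalization (equivalent to adding
`xi` to the heading); the noise interval is closed; a particle with exactly
zero force keeps its previous heading before noise; all forces are
evaluated from the time-`t` state before anyone moves; accumulation order
is ascending particle id, making runs bit-reproducible.

## Lyapunov estimators

Three independent estimators, designed to cross-check each other:

**Benettin tangent propagation** (`benettin_lle()`). The linearization

    dv_i(t+1) = v0 R(xi_i) (I - Fhat Fhat') (sum_{j in N_i} dv_j - beta dx_i) / |F_i|
    dx_i(t+1) = dx_i(t) + dv_i(t+1)

is co-evolved with the model using the *same* noise draws; the projector
orthogonal to `F_i` reflects the fixed speed (heading-only freedom); the
neighbor set is frozen from the base state (the rule is piecewise smooth —
neighbor-set switches are not differentiated). The 4N-dimensional
perturbation is renormalized every step, and
`lambda1 = mean(log alpha_t)` over post-transient steps. Convergence is
declared when the running mean varies by less than 2% (relative, with a
0.025 absolute scale floor) over the final third; the estimator is known to
stall at very small `beta`, and the result then carries
`converged = FALSE`.

**Gao–Zheng slope** (`gz_lambda()`). On the delay-embedded scalar series
`x(t) = X(t) + Y(t)` (center-of-mass coordinates summed; defaults `m = 6`,
delay 9 for swarm series), `Lambda(k) = <log(d_k/d_0)>` over vector pairs
initially closer than `r*` (default: 5th percentile of pair distances) and
separated in time by more than the Theiler window `(m-1)*tau + 1`. The
exponent is the slope of the initial linear segment, selected by maximizing
the fit R^2 among windows that stay below 90% of the curve's rise
(pre-saturation).

**Scale-dependent Lyapunov exponent** (`sdle()`). Pairs are grouped into
geometric shells (8 per decade) by their initial separation; each pair
contributes one-step log-growth increments until its separation exceeds
half the attractor size. Deterministic chaos shows a positive plateau
`lambda(eps)`; noise decays as `-gamma * log(eps)`; periodic motion stays
near zero. `classify_dynamics()` applies the half-decade plateau-width
criterion `log10(eps2/eps1) >= 1/2`, with plateau detection as the longest
run of consecutive shells within 10% of their median (a design choice — the
width criterion itself is the published one). Degenerate pair separations
(periodic series produce machine-precision distances) are floored at
`1e-8 * eps_max`.

The logistic map at full chaos (`lambda = log 2`) is the test oracle for
both embedded estimators; the tangent map is checked against finite
differences, and the compiled Benettin loop against an R-level replay.

## Correlation functions and the critical curves

Velocity fluctuations `dvhat_i` are mean-removed and normalized per frame
(`sum dvhat = 0`, `mean |dvhat|^2 = 1` — machine-precision sum rules). The
package computes the binned connected correlation `C(r, t)` in the
center-of-mass frame, the cumulative `Q(r)` whose first maximum gives the
correlation length `xi = r0` (first zero of `C`) and susceptibility
`chi = Q(r0)`, and the spectral correlation
`Chat(k, t) = (1/N) < sum_ij sinc(k r_ij) dvhat_i . dvhat_j >` with
`k_c = argmax_k Chat(k, 0)`, from one shared pair-distance histogram
(400 bins for the spectral transform; `max r / 50` for the binned `C(r)`;
self-pairs are included — at lag 0 they sit at `r = 0` and do not
contaminate `C(r > 0)`). Time origins are strided to a configurable budget
(default 20–25) and scalar observables are averaged over independent
realizations (default 3 seeds).

The correlation time `tau_k` solves `sum_{t>=1} sin(t/tau) g(t) / t = pi/4`
for the normalized dynamic correlation `g(t) = Chat(k_c, t)/Chat(k_c, 0)`.
The `t = 0` term of the sum is singular and its continuum contribution
vanishes, so it is excluded; for exponential `g` this equation reduces to
`arctan(tau0/tau) = pi/4`, recovering `tau = tau0` up to an `O(1/tau0)`
discretization bias. The objective oscillates spuriously at small `tau`,
so the solver brackets the *largest* root, where the objective decreases
through `pi/4`.

The critical confinement `beta_c(N; eta)` is the minimizer of
`tau_{k_c}(beta)` on a log-spaced grid, refined by a least-squares
parabola in `(log10 beta, log tau)` over a 5-point window around the grid
minimum (log-space fitting because `tau` carries multiplicative seed
noise); the location of the minimum of `t_m` (first zero of `g`) is
recorded as a cross-check. The susceptibility maximum `beta_m` is located
the same way on `log10 chi`, optionally on a separate wider grid evaluated
with a cheap static-only scan. Exponents: `nu` from `xi ~ beta_c^-nu`,
`gamma` from `chi(beta_m) ~ beta_m^-gamma`, `b` from `<W> ~ beta_c^b`,
`z` from `tau ~ k_c^-z`, `phi` from `lambda1 ~ beta_c^phi`, each fit by
least squares and by reduced major axis (`slope_RMA = sign(r) sd_y/sd_x =
slope_LS / |r|`, an identity asserted in the tests). `collapse_check()`
rescales NDCCF time axes by `k_c^z` and reports the mean absolute
inter-curve deviation on 50 grid points inside the scaled-time window
`(0, 4]`, and beyond it, documenting the partial character of the
collapse.

### Scaled-down study conditions

The package's acceptance analyses run the fixed-noise size sweep at
`eta = 0.5`, `N in {100, 200, 300, 500}`, 3 realizations per parameter
point, 4000 analysis steps after a 1000-step transient, 8-point
confinement grids per size, and NDCCF lags 0–120; the small-noise
unfolding uses `N = 100`, `eta in {0.1, ..., 0.5}`. These are roughly an
order of magnitude below the run lengths, realization counts and maximum
sizes used in published studies of the model, and the correlation-time
minima are correspondingly noisy; the estimator-design choices above
(log-parabola refinement, seed averaging) exist to make `beta_c` stable at
this scale. What passing tests at this scale show is that the pipeline
recovers planted power laws exactly and locates synthetic extrema to grid
resolution; what they cannot show is agreement of this exact update rule
with published exponent values — see the force-convention caveat above.
In this implementation the susceptibility `chi(beta)` at fixed `N` rises
monotonically through the weak-confinement regime and peaks only at
`beta = O(10)`, where the swarm is a coherently pulsating blob rather than
a near-critical chaotic swarm, so the `beta_c/beta_m` ratio of this rule
does not approach the small published value.

## Attractor characterization

`dq_spectrum()` computes generalized dimensions from order-q correlation
integrals `C_q(r) = mean_i p_i(r)^(q-1)` (self-pair included so `p_i > 0`
for negative `q`; `q = 1` via the entropy limit `mean_i log p_i`), with the
scaling window chosen per `q` as the best-R^2 linear stretch of at least
one decade; fits with `R^2 < 0.98` are flagged unreliable. Oracles: a
segment (`D_q = 1`), a disc (`D_q = 2`), and the two-scale Cantor measure
with weights `(p, 1-p)`, whose spectrum
`D_q = log(p^q + (1-p)^q) / ((q-1) log(1/3))` is analytic. The attractor's
Poincaré set is the 2D center-of-mass point `(X(t), Y(t))` sampled every
step after the transient — a planar set, consistent with nontrivial
`D_q <= 2` (a scalar reading would force `D_q <= 1`). Default transient for
multifractal sampling is 30,000 steps at full scale; tests use shorter,
labeled, runs.

`detect_period()` reports the smallest `p` with
`max_t |x(t+p) - x(t)| < tol * range(x)` (`tol = 1e-6` for deterministic
runs, `1e-2` for noisy recurrences); `count_clusters()` counts connected
components of the interaction graph at `link_distance = r0`;
`bifurcation_diagram()`, `phase_diagram()` and `classify_attractor()`
combine these with the Lyapunov machinery.

## Reproducibility

One master seed spawns named substreams (`init`, `noise`, `tangent`) via
`seed_streams()`, so noise realizations can be replayed — the Benettin
tangent dynamics depends on that. All particle loops accumulate in fixed
ascending-id order; identical configuration plus seed reproduces
trajectories bit-for-bit. Run provenance is captured by `run_manifest()`.

## Known limitations

- All-pairs neighbor search only; `O(N^2)` per step is fine for the sizes
  used here (`N <= 5000` at reduced lengths) but a cell list would be
  needed far beyond that.
- Strong-confinement (`beta >> 1`) quantities are convention-sensitive, as
  discussed above.
- `tau_k` estimates are truncated by the NDCCF lag window when `g(t)` does
  not reach zero inside it, which flattens the `tau(beta)` curve away from
  its minimum; the minimum location, which is what `beta_c` uses, is
  unaffected at the window sizes used.
- Trajectory output is text (CSV) and JSON only.
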