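# swarmchaos

Simulation and analysis of the two-dimensional **harmonically confined
Vicsek model** (HCVM): `N` self-propelled particles move at constant speed
`v0`, align with all particles inside a metric radius `r0`, receive a
uniform angular kick of width `eta`, and are pulled toward the origin by a
linear spring of strength `beta` — a minimal model for insect swarms that
form over a fixed marker, where confinement replaces the artificial
periodic box of the classical Vicsek model. The update rule is

```
F_i      = sum_{j : |x_j - x_i| < r0} v_j(t)  -  beta x_i(t)
v_i(t+1) = v0 R(xi_i) F_i / |F_i| ,   xi_i ~ U[-eta/2, eta/2]
x_i(t+1) = x_i(t) + v_i(t+1)
```

Depending on `beta` and `eta` the swarm settles on periodic, quasiperiodic
or chaotic attractors, and on a critical curve `beta_c(N; eta)` — located by
the minimum of the correlation time — the chaotic swarm becomes *scale
free*: the correlation length `xi` tracks the swarm size, and
`xi ~ beta^-nu`, `chi ~ beta^-gamma`, `<W> ~ beta^b`,
`tau_k ~ k_c^-z`, `lambda_1 ~ beta^phi` define static and dynamic critical
exponents of a phase transition reached as `beta -> 0`, `N -> infinity`.

The package is a tool for studying that transition end to end:

- **model core** — Rcpp-backed simulator (`hcvm_params()`,
  `simulate_hcvm()`, `cm_series()`), exact speed conservation,
  bit-reproducible seeded runs, replayable noise substreams;
- **Lyapunov exponents** — Benettin tangent-space propagation with shared
  noise (`benettin_lle()`, `tangent_step()`), the Gao–Zheng pair-separation
  slope (`gz_lambda()`), and the scale-dependent Lyapunov exponent with a
  chaos/noise classifier (`sdle()`, `classify_dynamics()`);
- **correlations** — connected velocity correlation functions in real and
  Fourier space, correlation length, susceptibility, polarization,
  correlation time via the `pi/4` condition (`cumulative_corr()`,
  `spectral_corr()`, `correlation_time()`);
- **criticality** — critical-curve location, LS/RMA power-law fits, the
  exponent suite (`critical_point()`, `exponent_suite()`,
  `noise_unfolding()`, `collapse_check()`);
- **attractors** — multifractal dimension spectra, period detection,
  cluster counts, bifurcation and phase diagrams (`dq_spectrum()`,
  `detect_period()`, `count_clusters()`, `phase_diagram()`).

Units: one time step is the observational sampling interval, one length is
the mean nearest-neighbor distance; `nondimensionalize()` converts measured
swarm constants (for the reference midge data, `v = 0.195` m/s,
`dt = 0.24` s, `r1 = 4.68` cm, giving `v0 = 1`).

## Worked example

Noise-induced chaos at the long-period window of the deterministic model
(`N = 128`, `beta = 99.52`; at `eta = 0` this orbit is non-chaotic, at
`eta = 0.5` it is not):

```r
library(swarmchaos)
params <- hcvm_params(n = 128, beta = 99.52, eta = 0.5)
params
#> <hcvm_params>  N = 128  beta = 99.52  eta = 0.5  v0 = 1  r0 = 0.472  [ focal_once ]

# tangent-space (microscopic) exponent
benettin_lle(params, n_steps = 6000, transient = 1000, seed = 1)
#> <lle_result>  lambda1 = 0.2026  ( 5000 steps, NOT converged )

# observable-scale exponent from the embedded center-of-mass series
traj <- simulate_hcvm(params, n_steps = 7000, transient = 1000,
                      seed = 1, record = "cm")
emb <- embed_series(cm_series(traj)$x_sum, m = 6, tau = 9)
gz_lambda(emb)
#> <gz_curve>  lle = 0.008489 +/- 0.00063  window = [ 4 , 49 ]  pairs = 50000
```

The positive tangent-space exponent (0.20 per step at this run length, with
the convergence flag still unset) says nearby *microstates* separate
quickly; the much smaller Gao–Zheng slope (0.008 per step) says the
center-of-mass observable decorrelates far more slowly — under this exact
update rule the two scales genuinely differ at strong confinement, which is
why the package reports both estimators rather than one number (see the
methods vignette, `vignettes/scale-free-chaos.Rmd`, for the force-convention
discussion behind this).

At `eta = 0` the same system gives `lambda1 ~ 1e-17` (non-positive:
a regular orbit), and the deterministic strong-confinement limit pulses
with period 2:

```r
p2 <- hcvm_params(n = 500, beta = 1e9, eta = 0)
tr <- simulate_hcvm(p2, 3300, transient = 3000, seed = 3, record = "cm")
detect_period(cm_series(tr)$x_sum, tol = 1e-3)
#> [1] 2
```

## Command line

```sh
inst/exec/swarmchaos simulate --config run.toml --out traj.csv
inst/exec/swarmchaos lle --config run.toml --method gz --out lle.json
inst/exec/swarmchaos critical-curve --n 500 --eta 0.5 \
    --beta-grid 1e-5:1e-2:8 --out cc.json
```

`run.toml` is a flat `[model]`/`[run]` key-value file; see `load_config()`.
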