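# hekf: constrained hybrid extended Kalman filtering with chi-squared validation for ODE models

`hekf` estimates unknown parameters of ordinary-differential-equation models
of biochemical systems from noisy, sparse, possibly non-uniformly sampled
time-course measurements — the situation of immunoblot or fluorescence
time courses — and, crucially, tells you whether the estimate deserves to be
believed.

## Who this is for

Modelers in systems biology who have (i) an ODE model `x' = f(x, u, t, θ)`
with unknown rate constants `θ`, (ii) discrete-time measurements
`y_k = h_k(x(t_k)) + v_k` of some output channels, and (iii) knowledge of the
measurement-noise covariance `R = diag(σ_1², …, σ_p²)` (fixed by the assay,
not by the analyst). The methods are general; three fixture models (a
reduced *E. coli* heat-shock response model, a no-spike variant of it, and a
generalized 18-parameter repressilator) and a synthetic-measurement generator
make everything runnable from scratch.

## The method

A three-stage pipeline:

1. **Constrained hybrid extended Kalman filter (HEKF).** The unknown
   parameters are appended to the state with zero time-derivative (*state
   extension*), so parameter estimation becomes state estimation. Between
   samples the filter integrates the nonlinear model ODE together with the
   differential Lyapunov equation `P' = F P + P Fᵀ + Q` (F the Jacobian along
   the estimate); at each sample it applies the linearized Kalman correction
   `x⁺ = x⁻ + K (y_k − h_k(x⁻))`, `K = P⁻Hᵀ(HP⁻Hᵀ + R_k)⁻¹`, per observed
   channel. Estimates violating linear constraints (e.g. positivity) are
   projected by the strictly convex QP
   `min (x − x⁺)ᵀ P⁺⁻¹ (x − x⁺) s.t. A x ≥ b`. The parameter estimate is the
   mean over the last 10 a-posteriori estimates.
2. **A-posteriori chi-squared identifiability test.** If the estimate θ̂ is
   right, the residuals `ê_j(t_k) = y_j(t_k) − ŷ_j(t_k)` are samples of the
   noise, so `S_j = (1/N_j) Σ_k ê_j(t_k)²` estimates `σ_j²` and
   `N_j S_j / σ_j² ~ χ²(N_j)`. The interval
   `[N_j S_j / q_{(1+γ)/2}, N_j S_j / q_{(1−γ)/2}]` covers `σ_j²` with
   probability γ; if the known `σ_j²` falls outside it on any channel, the
   estimate is rejected with confidence γ.
3. **Moment-matching refinement.** When stage 2 rejects (typical when the
   parameter space is large and the extended system unobservable), the
   estimate is refined by BFGS minimization of
   `Σ_j [ w1 (mean_j ê_j / σ_j)² + w2 ((S_j − σ_j²) / σ_j²)² ]` — matching the
   *noise moments* rather than fitting data points, which yields statistically
   consistent estimates by construction.

The same machinery discriminates among candidate models: run the filter per
candidate (parameters known, initial conditions possibly not), estimate each
channel's noise variance from the filter residuals, and discard candidates
whose chi-squared intervals exclude the known variances.

## Worked example

Estimate two parameters of the heat-shock fixture (both have true value 3)
from 22 noisy samples on the dense-then-sparse schedule:

```r
library(hekf)
e  <- heat_shock_experiment(seed = 1)   # simulate data + set up filter
pr <- run_pipeline(e$ext, e$data, e$cfg, gamma = 0.95)
pr
```

```
<pipeline_result: accepted at stage 'hekf'>
estimate:
   k_syn    k_seq
3.022478 2.920661
Chi-squared variance test (gamma = 0.95, df = N)
  x1       N=22  point=37.0034      interval=[22.1332, 74.1258]  true=50         pass
  x2       N=22  point=0.0141831    interval=[0.0084835, 0.028412]  true=0.02       pass
  overall: pass
```

The filter recovered `k_syn = 3.02`, `k_seq = 2.92` (true value 3, under 3%
error); both channels' variance intervals contain the true noise variances
(50 and 0.02), so the estimate is accepted at stage 2 and refinement is
skipped. With six free parameters (`heat_shock_large_experiment()`) the raw
filter estimate fails the test and stage 3 runs; the refined estimate passes.

Model discrimination between the spike and no-spike heat-shock variants:

```r
s   <- heat_shock_selection_experiment(seed = 2)
rep <- select_model(s$candidates, s$data, gamma = 0.95)
rep$retained    # "heat_shock"
rep$rejected    # "heat_shock_nospike"
```

## Command line

```sh
exec/hekf simulate --model heat_shock --out data.csv --seed 1
exec/hekf estimate --model heat_shock --data data.csv --out report.json
exec/hekf validate --model heat_shock --data data.csv --params 3,3
exec/hekf select   --models heat_shock,heat_shock_nospike --data data.csv
```

Exit status: 0 success / test passed, 3 a test-failure verdict, 2 usage
error, 1 runtime error. Measurement CSVs carry a `time` column plus one
column per channel (empty cell = unobserved) and a sidecar JSON with `R`,
seed and provenance.

## Vignette

`vignettes/hekf-methods.Rmd` documents the model assumptions, every tunable
parameter with its default and rationale, what the synthetic-data generator
does and does not emulate, numerical choices, and known limitations.
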