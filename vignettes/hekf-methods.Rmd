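---
title: "Methods: constrained hybrid EKF, chi-squared validation, and moment matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained hybrid EKF, chi-squared validation, and moment matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hekf)
```

This vignette is the package's own account of its science: the models and
their assumptions, every tunable parameter with units, default and rationale,
what the synthetic-data generator emulates (and does not), the numerical
choices, and the design decisions that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Problem setting and assumptions

We consider a continuous-time process `x'(t) = f(x, u, t, θ)` with state `x`
(concentrations or molecule counts), external input `u(t)` (e.g. a
temperature regime), and unknown constant parameters `θ`, observed at
discrete, possibly non-uniform instants through per-time output maps
`y_k = h_k(x(t_k)) + v_k`. Assumptions baked into the package:

* **Measurement noise is additive, zero-mean Gaussian, channel-independent,
  with known variances** `R = diag(σ_j²)`. Everything downstream — the
  chi-squared test, the moment-matching objective, model selection — anchors
  on `R` being known. `R` is a property of the assay; the package never
  estimates it from the data.
* **Process noise `Q`** is not a physical quantity here but a diagonal
  "model-confidence" covariance that regularizes the filter; larger entries
  mean less trust in the equations.
* The noise mean is known to be zero, so the variance point estimate uses the
  zero-mean sum of squares with **N (not N−1) degrees of freedom** (no sample
  mean is estimated). An `N-1` convention is available via the `df` argument
  of `variance_interval()`/`chi2_test()` for users who prefer it.

## 2. The filter

State extension turns parameters into states with zero derivative, ordered
**dynamic states first, then free parameters in declaration order**; all
covariances follow this ordering. Prediction integrates the extended ODE and
the differential Lyapunov equation `P' = F P + P Fᵀ + Q` as one stacked
system, with `F` re-evaluated along the evolving estimate (not frozen at the
interval start); correction is the standard linearized update restricted to
the channels observed at that instant. Key choices:

* **Covariance hygiene.** The update `P⁺ = (I − K H) P⁻` is ill-conditioned;
  the package symmetrizes after every propagation/update and floors tiny
  negative eigenvalues at zero. Eigenvalues below `−1e−8 × scale` indicate
  genuine breakdown and flag divergence (we use a relative floor rather than
  the stricter absolute `−1e−10`, which false-alarmed on well-behaved
  24-dimensional runs). A Joseph-form update is available
  (`filter_config(joseph = TRUE)`); the default is the plain form for
  fidelity to the usual recursion.
* **Divergence policy.** Non-finite estimates, innovation-covariance
  condition number above `1e12`, or integration failure set `diverged = TRUE`
  and retain the partial trajectory rather than raising — downstream stages
  (pipeline, model selection) handle the flag.
* **Constraints.** Fixtures constrain the whole extended state to be
  nonnegative (counts and rates are positive). Projection solves the strictly
  convex QP `min (x − x⁺)ᵀ P⁺⁻¹ (x − x⁺)` over the feasible set via the
  Goldfarb–Idnani dual active-set method (`quadprog`); feasible estimates
  pass through bitwise-unchanged. Feasibility of a constraint set is checked
  at construction.
* **Initial covariance `P0`.** No canonical choice exists; the package
  default is `diag(pmax(x0², 1))` — squared initial-guess magnitudes floored
  at 1. The fixture experiments override the parameter block with
  `(0.5 × guess)²` (heat-shock large case, repressilator) or a fixed spread
  of 4 (2-parameter case, guesses of 1 against truth 3), reflecting honest
  prior uncertainty about the guesses.
* **Final estimate.** Mean of the parameter components over the last 10
  constrained a-posteriori estimates (`averaging_window = 10`), extracting a
  single number from the oscillating converged track.

## 3. The chi-squared test

For each channel, `S_j = (1/N_j) Σ ê_j²` and the interval
`[N_j S_j / q_{(1+γ)/2,N_j}, N_j S_j / q_{(1−γ)/2,N_j}]`. The estimate passes
only if every channel's interval contains the known `σ_j²`; no
multiple-testing correction is applied across channels (the per-channel
check with conjunction is the procedure's definition). Default `γ = 0.95`;
0.9 and 0.997 are the other conventional values. Predictions default to the
**model solution at the estimated parameters** (initial conditions assumed
known); `predict_outputs_filter()` supplies filter-state predictions instead,
which is what model selection uses so unknown initial conditions are
tolerated. `S_j = 0` (exactly zero residuals) yields a degenerate `[0, 0]`
interval and is flagged in the report.

A note on filter-state predictions: a-posteriori estimates have already seen
`y_k`, so their residuals are mildly shrunk relative to the noise (the effect
shrinks with `Q`). At the fixtures' `Q` this stays well inside the interval
for the generating model while wrong models still fail loudly; the test
suite's selection experiment quantifies the operating characteristics
(≈ 95% retention of the true model at γ = 0.95, 100% rejection of the
no-spike variant over the tested seeds).

## 4. Moment matching

`moment_matching_cost()` is dimensionless by construction: the mean term is
scaled by `σ_j`, the variance term by `σ_j²`, so channels of different
magnitudes weigh equally. Defaults `w1 = w2 = 1` (equal weights; the
repressilator experiment's published design uses equal weights and no value
is printed for the heat-shock run). Choices:

* **Log-parameter space by default**: rate constants are positive, so
  optimizing `log θ` enforces positivity without constraints and equalizes
  scales across rates spanning orders of magnitude. `transform = "identity"`
  is available.
* **BFGS with numerical gradients** (`stats::optim`), deterministic given the
  start and data. Budget `maxit = 500` by default. For large ill-conditioned
  problems the budget can be spent in blocks with the quasi-Newton recursion
  restarted between them (`restart_every`), optionally with an early exit once
  the cost falls below `target_cost`; on the 18-rate oscillator a single stale
  BFGS run stalls on a ridge that restarts escape.
* **ODE-failure sentinel**: a trial `θ` where the model cannot be integrated
  returns a large finite penalty instead of raising, so line searches
  survive. The sentinel is escalated per run to `max(penalty, 1000 × start
  cost)`; a fixed sentinel below the genuine start cost would make failure
  regions look like progress (observed on the repressilator, where a poor
  start costs ~10⁶). The per-evaluation integrator gets a modest step budget
  (`max_steps = 2e4`) so pathological parameters fail fast.
* **Monotone improvement** is guaranteed by returning the start if the
  optimizer ends worse; `cost ≤ start_cost` always holds in the result.

The pipeline (`run_pipeline()`) accepts the filter estimate if stage 2
passes, otherwise refines from it ("begins where the filter left off"); a
diverged filter falls through to refinement from the best available iterate.

## 5. Fixtures and the synthetic-data generator

All experiment data are generated in silico: solve the fixture ODE at its
true parameters, evaluate the measured channels at the schedule, add
independent zero-mean Gaussian noise of the stated variances. The generator
reproduces exactly this design (`simulate_measurements()`), including a
relative-noise mode (variance = fraction × signal mean) used by the
repressilator experiment. It does **not** emulate intrinsic (demographic)
stochasticity, non-Gaussian or correlated noise, or missingness mechanisms —
a green test establishes correctness of the method under its own stated
noise model, not robustness beyond it.

**Heat-shock fixture (3 states: chaperones D, sigma-32 S, unfolded proteins
U).** The published reduced-order model's coefficients are not reproduced in
the source text available to this package, so the fixture uses **nominal
surrogate values** chosen once to reproduce the described phenomenology and
then frozen: temperature step at `t = 0`; rapid post-shock accumulation of D
and S with a transient S spike (peak ≈ 4.8 at `t ≈ 2` versus a settled 2.29);
settling within ≈ 50 minutes; ≈ 14× induction of both outputs. The two
parameters estimated in the small case, `k_syn` (chaperone synthesis per
sigma-32) and `k_seq` (chaperone-mediated sigma-32 degradation), have true
value 3. Noise variances `R = c(50, 0.02)` — noise sd ≈ 5% of each channel's
post-shock steady state — are likewise surrogate choices. The no-spike
variant replaces the titration-modulated degradation `k_seq φ(U) D S`
(φ(U) = K_u/(K_u+U)) with a constant-rate degradation derived from the same
parameters' post-shock fixed point, so both models share the post-shock
steady state and differ only in the transient; the derived rate is frozen at
construction, which is why that fixture is meant for known-parameter state
estimation (model selection), not for estimating degradation parameters.

**Sampling.** The 22-point dense-then-sparse schedule uses 7 dense instants
`(1, 2, 4, 7, 12, 20, 35)` inside the transient — the exact dense instants
are a package choice; the normative features are the count (22) and the
uniform 25-minute tail to 400 minutes. The repressilator uses 30 equally
spaced points over 30 time units (≈ 3 periods of the default cycle).

**Repressilator (6 states, 18 rates).** Each gene/protein pair has its own
transcription rate `a_i`, repression threshold `K_i`, Hill exponent `h_i`,
mRNA decay `b_i`, translation `c_i` and protein decay `g_i`, with cyclic
repression `p_0 = p_3`. Defaults `a = 216, K = 1, h = 2, b = 1, c = g = 5`
(identical across pairs) with asymmetric initial conditions put the system on
a limit cycle of period ≈ 9.6; identical pair rates make the three mRNAs
cyclic time-shifted copies, which the tests exploit as a symmetry oracle.
The relative noise fraction defaults to 5% of the signal mean (the printed
fraction is not recoverable from the source text).

**Experiment configurations.** Initial guesses are deliberately offset from
the truth: `(1, 1)` against `(3, 3)` in the 2-parameter case; `1.5 × truth`
in the 6- and 18-parameter cases. Process noise defaults: `q_states = 1e-6`
(the model equations are exact in these experiments), parameter entries
`0.05` (2-parameter case) or `(0.05 × guess)²` (large cases — with rates
spanning four orders of magnitude, absolute values would be meaningless).
These were chosen once from standard practice and frozen; they are method
configuration, not acceptance tuning.

## 6. Numerical choices

* **Integrator.** No ODE solver package exists in the runtime environment,
  so the package carries an adaptive Dormand–Prince RK5(4) with cubic Hermite
  dense output. The fixture dynamics are smooth and at most mildly fast–slow,
  so an explicit pair at tight tolerance is adequate; a stiff implicit method
  would be preferable for genuinely stiff user models and is a known
  limitation. Defaults: `rtol = 1e-8`, `atol = 1e-10` for simulation and
  prediction; the filter and the refinement objective default to `1e-6`/
  `1e-8` for runtime, configurable everywhere.
* **Jacobians.** Analytic when the model supplies them (all fixtures do —
  they double as oracles for the tests); otherwise central finite differences
  with per-component step `sqrt(machine eps) × max(|x_i|, 1)`. Parameter rows
  of the extended Jacobian are exactly zero by construction, never
  differenced.
* **Gain computation** uses a linear solve against the innovation covariance,
  never an explicit inverse.
* **Ties and degenerate inputs.** Model selection breaks ties among retained
  candidates by the sum of relative absolute deviations
  `Σ_j |S_j − σ_j²| / σ_j²` (the selection rule "closest variances" needs a
  metric; this is the package's). Empty candidate lists, empty series,
  non-monotone times, zero R entries and windows longer than the series are
  rejected with informative errors.

## 7. Known limitations

* Explicit integrator: very stiff user models will integrate slowly or fail;
  tolerances and step budgets are configurable but the method family is not.
* The chi-squared test checks second-moment consistency only; it cannot
  detect miscalibrated noise *distributions* with the correct variance.
* Filter-state predictions shrink residuals slightly (Section 3); with very
  large `Q` the test based on them would be anti-conservative toward
  acceptance.
* Moment matching inherits BFGS's local character: from a poor start on an
  oscillatory model the descent can need thousands of evaluations (the
  18-parameter repressilator refinement is the package's stress case, and the
  published experiment it mirrors also ran to ~720 BFGS iterations). A
  multi-start loop is left to the user by design.
* The no-spike heat-shock variant freezes its derived degradation rate at
  construction (Section 5).
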