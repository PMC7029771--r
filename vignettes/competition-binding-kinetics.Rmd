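---
title: "Models and methods: simulating and fitting competition association assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and fitting competition association assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinbind)
```

## The problem

Competition association assays (kinetic probe competition assays, kPCA)
measure the time course of a labelled tracer binding its target while an
unlabelled test compound competes for the same site. Fitting those traces to
the Motulsky–Mahan "kinetics of competitive binding" model yields the
compound's association rate constant $k_3$ (often written $k_{on}$,
M$^{-1}$s$^{-1}$) and dissociation rate constant $k_4$ ($k_{off}$, s$^{-1}$),
hence the kinetic affinity $K_D = k_4/k_3$ and residence time $RT = 1/k_4$.
In practice the fit degrades in reproducible ways — very slow dissociators
pin only $k_{on}$, very fast dissociators pin only $K_D$ — and the crossover
points depend on the assay design. `kinbind` exists to quantify exactly
that: it simulates whole assay plates under configurable designs, noise and
systematic errors, refits them, and reports the precision (CV) and accuracy
(relative error) of the recovered constants over Monte Carlo replicates.

## The binding model

For a tracer at constant free concentration $L$ with rate constants
$k_1, k_2$ and a compound at constant free concentration $I$ with
$k_3, k_4$ (no ligand or target depletion anywhere in this package), the
bound-tracer trajectory is a sum of two exponentials with observed rates

$$K_A = k_1 L + k_2, \quad K_B = k_3 I + k_4,$$
$$K_{F,S} = \tfrac12\Big[K_A + K_B \pm \sqrt{(K_A - K_B)^2 + 4 k_1 k_3 L I}\Big].$$

The raw signal is $y(t) = y_0 + B_{max}\,occ(t)$ where $occ(t)$ is the
closed-form occupancy (`specific_binding_trace()`). Two identities anchor
the implementation and are enforced by tests: $K_F + K_S = K_A + K_B$ and
$K_F K_S = k_1 L k_4 + k_2 k_3 I + k_2 k_4$. The second is also how $K_S$ is
computed (product form), which avoids catastrophic cancellation when
$K_F \gg K_S$. For the measure-zero degenerate case $K_F \approx K_S$
(possible only as $I \to 0$), the implementation perturbs $K_S$ by
$10^{-8} K_F$ rather than switching to the confluent analytic limit; the
induced error is below $10^{-6}$ and the output stays finite.

The **normalised model** (`normalized_compound_binding_trace()`) divides the
specific signal by the vehicle-control (tracer-only) trace at the same time
point and inverts it to percent compound binding; $B_{max}$ and $y_0$ cancel,
and with them any multiplicative signal drift shared by all wells. The model
is defined piecewise as exactly 0 at $t = 0$ (the ratio is 0/0 there), and
$t = 0$ points are excluded from every kinetic fit for the same reason.

An independent mass-action ODE integrator (`mechanism_ode_trace()`, via
`deSolve::lsoda`) serves as the numerical oracle for the closed form (they
agree to better than $10^{-5}$ relative over the tested parameter space) and
extends the simulator to irreversible ($k_4 = 0$) and induced-fit
($R + I \rightleftharpoons RI \rightleftharpoons R'I$) mechanisms. The
induced-fit isomerisation rates default to $10^{-2}/10^{-3}$ s$^{-1}$ and
are configurable.

## The simulator and its defaults

`simulate_kpca()` generates one plate: one trace per nonzero dose, plus
replicated vehicle (100% tracer binding) and background (0%) control wells.
The defaults define the reference study conditions used throughout:

* tracer 12.5 nM with $k_1 = 2.56\times10^6$ M$^{-1}$s$^{-1}$,
  $k_2 = 1.67\times10^{-3}$ s$^{-1}$ ($K_{D1} \approx 0.65$ nM) —
  `standard_tracer()`;
* 400 s observation, 10 s measuring interval (grid
  $10, 20, \dots, 400$ s);
* dose series 0 (vehicle), 2.5, 25, 250, 2500 nM — a 10-fold series
  bracketing a 250 nM mid dose;
* additive Gaussian noise, identical for all wells and time points, with
  SD equal to 1% of the assay window (vehicle-control equilibrium signal
  minus background). The 1% figure is this package's declared default for
  a well-behaved fluorescence assay; it is fully configurable, and all
  quantitative Monte Carlo outcomes scale with it;
* three control replicates per plate (used for normalisation means and
  Z'-factor estimation).

What the generator deliberately does **not** emulate: plate-geometry or
liquid-handling artefacts, heteroscedastic or multiplicative noise, and
ligand/target depletion. Passing tests therefore demonstrate correctness of
the estimators under the stated noise law, not robustness to every
real-plate pathology.

Reproducibility contract: every stochastic function takes a seed; studies
take one master seed and derive a per-(condition, replicate) sub-seed by a
fixed counter formula (`derive_seed()`), so replicate $r$ of condition $c$
is bitwise identical regardless of how many other conditions or replicates
are run.

Systematic errors are injected with `perturbation_spec()`: the data are
*generated* with perturbed compound doses, tracer concentration or tracer
rate constants while the *fit* uses the nominal values — the classic
evaluate-with-wrong-inputs scenario. One structural fact worth knowing: a
multiplicative dose error applied to **all** wells is absorbed exactly by
the globally shared $k_3$ (the model depends on $k_3$ only through
$k_3 I$), so it biases $k_3$ by the error factor while leaving perfect
residuals. Only non-uniform errors (e.g. a single mis-pipetted well) leave
a residual pattern; `residual_run_statistic()` — the longest same-sign
residual run within a trace — is the package's detection signal, compared
against the 95th percentile of its unperturbed distribution.

## Fitting

All fitters share one engine:

* **Parameterisation.** Rate constants are fitted as $\log_{10}$ values
  with box bounds $\log_{10} k_{on} \in [2, 11]$,
  $\log_{10} k_{off} \in [-8, 2]$ — positivity plus scale invariance across
  the decades-wide compound space.
* **Variable projection.** Parameters that enter the model linearly
  ($y_0$, $B_{max}$, dose–response top/bottom) are solved exactly by linear
  least squares inside the residual callback, so the nonlinear search runs
  over only the rate dimensions (plus $K_{Drift}$ where applicable). This
  makes the fits faster and markedly more robust to poor starts; reported
  standard errors are nevertheless computed from the full-parameter
  Jacobian at the optimum.
* **Deterministic multi-start.** Levenberg–Marquardt (`minpack.lm::nls.lm`)
  from a fixed $5\times5$ log-spaced grid over the interior of the bounds;
  the lowest-SSE converged solution wins; ties within $10^{-9}$ relative
  SSE go to the smaller $k_4$. There is no randomness in optimisation:
  identical data give identical fits.
* **Ill-determinedness flag.** A rate parameter is flagged when its 95%
  confidence interval in $\log_{10}$ space spans more than two decades.
  The covariance is evaluated at a noise level of
  $\max(\text{residual SD}, 1\%\ \text{of signal SD})$: the floor makes the
  flag answer "could this parameter be pinned under nominal assay noise?",
  which is the operative question and keeps the diagnostic meaningful on
  noise-free data, where the raw residual SD is numerically zero. Reported
  standard errors always use the observed residual SD.

The five fitters are `fit_kpca_global()` (raw traces; shared $k_3, k_4,
B_{max}, y_0$), `fit_kpca_normalized()` (only $k_3, k_4$),
`fit_kpca_drift()` (adds $K_{Drift} \ge 0$, a multiplicative
$e^{-K_{Drift} t}$ on the background-subtracted signal — the simplest decay
law consistent with a fitted rate constant in s$^{-1}$; real photobleaching
is often not mono-exponential, which is precisely why the normalised fit
exists as the more general alternative), `fit_association_global()` and
`fit_assoc_then_dissoc_global()` (tracer characterisation across
concentrations, shared $k_{on}, k_{off}, B_{max}$). Dose–response curves use
a one-site competition model with the Hill slope fixed at 1 (consistent with
the 1:1 mechanism; a free slope is deliberately not the default) and convert
IC$_{50}$ to affinity via Cheng–Prusoff, $K_{D,app} = IC_{50}/(1 + L/K_{D1})$.

Whether the original analyses floated $B_{max}$ per trace or shared it is
not documented anywhere we could find; this package shares it, which is the
stronger and simpler assumption and is validated by the round-trip tests.

## Statistics

`summarize_mc()` reports per parameter: mean, SD, CV$\% = 100\,SD/mean$,
signed relative error $\% = 100\,(true - mean)/true$, plus median and MAD as
robust companions — means are fragile when ill-determined replicates drift
to the parameter bounds, but means remain the primary headline statistic.
Non-converged replicates are counted and excluded from moments;
ill-determined replicates are included in the primary moments and excluded
in a parallel `*_excl_ill` set, since published aggregates rarely state
which convention they used. `zprime()` and `bland_altman_log10()` implement
the standard assay-quality and method-comparison statistics.

## The Monte Carlo studies

* `run_rate_grid_study()` — default $7\times5$ decade grid
  ($k_3 \in 10^3..10^9$, $k_4 \in 10^{-5}..10^{-1}$), 100 replicates per
  compound. Expected behaviour, confirmed by the acceptance tests: for
  $k_4 \in [10^{-3}, 10^{-1}]$ both rates and $K_D$ come back accurately
  (known exceptions: compounds whose traces collapse onto a control trace,
  prominently $10^4$–$0.1$ and $10^9$–$0.01$, and more broadly the
  $k_3 = 10^9$ column at this dose series); for $k_4 \le 10^{-4}$ only
  $k_3$ is reliable; for $k_4 \gtrsim$ the sampling rate only $K_D$ is.
* `run_condition_sweep()` — one axis at a time: observation time,
  measuring interval, tracer concentration, tracer $k_1$ or $k_2$. Longer
  observation rescues slow off-rates (the observation time bounds the
  longest quantifiable residence time); faster sampling rescues fast
  off-rates; 10× tracer concentration and 10× tracer $k_1$ produce
  identical traces and identical (modest) improvements.
* `run_epca_incubation_study()` — endpoint dose–response at incubation
  times of 1–24 h (the package's declared grid for this protocol), fitted
  and Cheng–Prusoff-converted to apparent $K_D$. Finite incubation inflates
  the apparent $K_D$ of slow binders: for a $k_4 = 10^{-5}$ s$^{-1}$
  compound the inflation on this grid is ~19/9.6/5.0/2.7-fold at 1/2/4/8 h
  (≈ 2.7-fold at the grid point nearest half the residence time, growing
  steeply below it), reaching ≥ 3-fold for incubations of a quarter
  residence time and shorter.
* `run_error_signature_study()` — injected systematic errors and wrong
  mechanisms for one slow ($k_4 = 10^{-4}$, 1600 s/10 s) and one fast
  ($k_4 = 10^{-2}$, 400 s/10 s) reference scenario.
* `run_tracer_method_comparison()` — association-only vs
  association-then-dissociation tracer characterisation over a tracer grid
  (defaults: $L$ = 3.125/12.5/50 nM, 1200 s window, chase at 600 s — this
  package's declared design for the comparison).

Problem sizes in the shipped acceptance script were chosen to stabilise the
reported means (50–500 replicates per condition, as stated per target) while
remaining desk-scale.

## Numerical choices and known limitations

* Unweighted least squares throughout, matching the homoscedastic noise
  model; weighting hooks are deliberately absent.
* LM iteration cap of 60 per start; termination codes 1–4 count as
  converged, and a run where no start converges raises a typed
  non-convergence error that studies record per replicate rather than
  abort on.
* The numerical Jacobian uses central differences with a step of
  $10^{-5}$ in the fitted scale.
* The equilibrium limit of the kinetic model is used as its own oracle at
  $t = 50/K_S$; agreement to $10^{-4}$ relative is part of the test suite.
* Not implemented (out of scope by design): ligand/target depletion,
  two-state tracer binding, alternative ligand-addition scheduling,
  nonspecific-binding plateaus, heteroscedastic noise, vendor file formats.
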