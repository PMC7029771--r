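# kinbind

Simulation and global fitting of competition association binding kinetics.

Drug discovery labs quantify how fast a compound binds (k<sub>on</sub>,
M⁻¹s⁻¹) and leaves (k<sub>off</sub>, s⁻¹) its target with **kinetic probe
competition assays** (kPCA): a labelled tracer and the unlabelled compound
bind the target simultaneously, the tracer signal is followed over time at
several compound doses, and all traces are fitted globally to the
Motulsky–Mahan *kinetics of competitive binding* model. The bound-tracer
trajectory is bi-exponential with observed rates

    KA = k1·L + k2          KB = k3·I + k4
    KF,KS = ½ [ KA + KB ± √((KA − KB)² + 4·k1·k3·L·I) ]

where k1, k2, L describe the tracer, and k3, k4, I the compound. The
fit is well-behaved only in part of rate space: when the compound's
residence time (1/k4) exceeds the observation window only k3 is
identified, and when k4 outruns the sampling interval only the affinity
KD = k4/k3 is. `kinbind` is a toolkit for mapping, understanding and
engineering around those limits:

* closed-form and ODE evaluation of the competition model (raw,
  normalised/amplitude-free, and signal-drift-corrected variants),
  pseudo-first-order association and association-then-dissociation tracer
  models, plus irreversible and induced-fit mechanisms;
* a Monte Carlo plate simulator with controls, additive Gaussian noise and
  injectable systematic errors (wrong doses, wrong tracer parameters,
  wrong mechanism);
* deterministic multi-start global least-squares fitters with
  ill-determinedness diagnostics, and equilibrium dose–response fitting
  with Cheng–Prusoff conversion;
* precision/accuracy metrics (CV, relative error, Z′-factor, Bland–Altman
  log differences) and ready-made study drivers (rate grids, design sweeps,
  incubation-time studies, error signatures, tracer-method comparison).

It is aimed at assay developers and in vitro pharmacologists who want to
check what their kPCA/ePCA design can and cannot measure before running it.

## Worked example

Simulate a standard plate (12.5 nM tracer, k1 = 2.56×10⁶ M⁻¹s⁻¹,
k2 = 1.67×10⁻³ s⁻¹; 400 s observation at 10 s intervals; doses 2.5–2500 nM
plus vehicle; noise SD = 1% of the assay window) for a compound with
k3 = 10⁶ M⁻¹s⁻¹ and k4 = 10⁻² s⁻¹, then refit it:

```r
library(kinbind)

tracer   <- standard_tracer()
compound <- compound_spec(k3 = 1e6, k4 = 1e-2)
plate    <- simulate_kpca(assay_design(), tracer, compound,
                          noise_model(sd_fraction = 0.01), seed = 42)
fit_kpca_global(plate)
```

```
<fit_result> converged = TRUE, SSE = 0.0233493, n = 280 (25 starts)
 parameter   estimate       se  scale      ci_lo     ci_hi ill_determined
        k3  9.761e+05 0.009887  log10  9.335e+05 1.021e+06          FALSE
        k4  9.791e-03 0.011764  log10  9.285e-03 1.032e-02          FALSE
       KD2  1.003e-08 0.004388  log10  9.834e-09 1.023e-08          FALSE
        y0 -1.925e-03 0.001472 linear -4.810e-03 9.611e-04             NA
      Bmax  1.002e+00 0.001736 linear  9.986e-01 1.005e+00             NA
```

The true rates are recovered within ~2.5% (k3 = 0.976×10⁶, k4 =
0.979×10⁻²); the rate SEs are on the log10 scale, so the 95% CI of k3 spans
10^(±1.96·0.0099) ≈ ±4.5%. No parameter is flagged `ill_determined`.

Monte Carlo precision/accuracy for any compound set is one call:

```r
res <- run_rate_grid_study(data.frame(k3 = 1e6, k4 = c(1e-2, 1e-4)),
                           n_rep = 100, seed = 1)
subset(res$summary, parameter == "k4", c(k4_true, mean, cv_pct, rel_err_pct))
```

```
  k4_true         mean    cv_pct rel_err_pct
2   1e-02 0.0100424021  3.172419  -0.4240209
5   1e-04 0.0001046934 45.293009  -4.6933809
```

The k4 = 10⁻² compound is recovered with 3% CV and a −0.4% relative error;
the k4 = 10⁻⁴ compound — residence time 25× the observation window — shows
the characteristic slow-off-rate breakdown (CV 45%), while its k3 (not
shown) is still recovered to within a fraction of a percent.

A YAML-driven command line sits in `inst/cli/kinbind.R`
(`Rscript inst/cli/kinbind.R grid-study --config inst/extdata/example_study.yaml --out-dir out`).

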