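# Config-driven Monte Carlo studies: each study is a pure function of its
# inputs and a master seed. Replicate r of condition c always draws its
# noise from the sub-seed derive_seed(master, (c-1)*1e5 + r), so results are
# bitwise reproducible and independent of how many other conditions run.

#' Standard tracer used throughout the examples and default studies
#'
#' 12.5 nM tracer with k1 = 2.56e6 M^-1 s^-1 and k2 = 1.67e-3 s^-1
#' (KD1 ~ 0.65 nM), the reference probe of the standard kPCA set-up.
#'
#' @return A [tracer_spec()].
#' @export
standard_tracer <- function() tracer_spec(L = 12.5e-9, k1 = 2.56e6, k2 = 1.67e-3)

#' Default 35-compound rate grid
#'
#' Log grid `k3` in 1e3..1e9 (decades) x `k4` in 1e-5..1e-1 (decades),
#' covering the physiologically meaningful on/off-rate space including the
#' known problematic corner combinations.
#'
#' @return A data.frame with columns `k3`, `k4`.
#' @export
default_rate_grid <- function() {
  g <- expand.grid(k3 = 10^(3:9), k4 = 10^(-5:-1))
  g[order(g$k3, g$k4), , drop = FALSE]
}

.mc_counter <- 100000  # sub-seed stride per condition

# run n_rep kPCA simulate+fit replicates for one condition; errors become
# per-run records, never aborts
.mc_kpca_condition <- function(tracer, compound, design, noise, n_rep,
                               master_seed, condition_index,
                               fitter = fit_kpca_global, perturbation = NULL,
                               maxiter = 60) {
  fits <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    seed_r <- derive_seed(master_seed, (condition_index - 1) * .mc_counter + r)
    fits[[r]] <- tryCatch({
      ts <- simulate_kpca(design, tracer, compound, noise,
                          perturbation = perturbation, seed = seed_r)
      fitter(ts, tracer = tracer, maxiter = maxiter)
    }, error = function(e) e)
  }
  fits
}

.estimates_table <- function(fits, id_cols) {
  rows <- lapply(seq_along(fits), function(r) {
    f <- fits[[r]]
    if (inherits(f, "fit_result")) {
      data.frame(id_cols, replicate = r,
                 k3_hat = unname(f$estimates["k3"]),
                 k4_hat = unname(f$estimates["k4"]),
                 kd2_hat = unname(f$estimates["KD2"]),
                 converged = f$converged,
                 ill_k4 = isTRUE(f$ill_determined["k4"]),
                 run_stat = if (!is.null(f$residuals)) residual_run_statistic(f) else NA_integer_,
                 error = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(id_cols, replicate = r, k3_hat = NA_real_, k4_hat = NA_real_,
                 kd2_hat = NA_real_, converged = FALSE, ill_k4 = NA,
                 run_stat = NA_integer_, error = conditionMessage(f),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Monte Carlo rate-grid study
#'
#' Simulates and refits competition association experiments for a grid of
#' virtual compounds under one assay design, quantifying per-compound
#' precision (CV) and accuracy (relative error) of `k3`, `k4` and `KD2`.
#'
#' @param compounds data.frame with columns `k3`, `k4` (default:
#'   [default_rate_grid()]).
#' @param tracer A [tracer_spec()].
#' @param design An [assay_design()].
#' @param noise A [noise_model()].
#' @param n_rep Replicates per compound (default 100).
#' @param seed Master seed.
#' @param fitter Fit function for raw trace sets (default
#'   [fit_kpca_global()]).
#' @return A list with `summary` (one row per compound x parameter) and
#'   `estimates` (one row per compound x replicate, the rate-plot data).
#' @export
run_rate_grid_study <- function(compounds = default_rate_grid(),
                                tracer = standard_tracer(),
                                design = assay_design(), noise = noise_model(),
                                n_rep = 100, seed = 1,
                                fitter = fit_kpca_global) {
  stopifnot(n_rep >= 1, all(c("k3", "k4") %in% names(compounds)))
  summaries <- list(); estimates <- list()
  for (i in seq_len(nrow(compounds))) {
    cp <- compound_spec(compounds$k3[i], compounds$k4[i])
    fits <- .mc_kpca_condition(tracer, cp, design, noise, n_rep, seed, i,
                               fitter = fitter)
    id <- data.frame(compound = i, k3_true = cp$k3, k4_true = cp$k4)
    estimates[[i]] <- .estimates_table(fits, id)
    sm <- summarize_mc(fits, list(k3 = cp$k3, k4 = cp$k4, KD2 = cp$KD2))
    summaries[[i]] <- cbind(id[rep(1, nrow(sm)), , drop = FALSE], sm,
                            row.names = NULL)
  }
  list(summary = do.call(rbind, summaries),
       estimates = do.call(rbind, estimates))
}

#' Monte Carlo sweep of one assay-design axis
#'
#' Repeats the rate-grid protocol for exemplar compounds while sweeping a
#' single assay parameter: total observation time, measuring interval,
#' tracer concentration, tracer `k1` or tracer `k2`.
#'
#' @param axis One of `"observation_time"`, `"interval"`, `"tracer_conc"`,
#'   `"tracer_k1"`, `"tracer_k2"`.
#' @param values Values of the swept axis (seconds, molar, or rate units).
#' @param compounds data.frame `k3`, `k4`; defaults to the slow- and
#'   fast-dissociating exemplars (1e6, 1e-4) and (1e6, 1e-1).
#' @inheritParams run_rate_grid_study
#' @return A data.frame: one row per swept value x compound x parameter.
#' @export
run_condition_sweep <- function(axis = c("observation_time", "interval",
                                         "tracer_conc", "tracer_k1", "tracer_k2"),
                                values,
                                compounds = data.frame(k3 = c(1e6, 1e6),
                                                       k4 = c(1e-4, 1e-1)),
                                tracer = standard_tracer(),
                                design = assay_design(), noise = noise_model(),
                                n_rep = 100, seed = 1,
                                fitter = fit_kpca_global) {
  axis <- match.arg(axis)
  out <- list(); cond <- 0
  for (v in values) {
    dsn <- design; trc <- tracer
    switch(axis,
      observation_time = { dsn <- assay_design(v, design$interval, design$dose_series,
                                               design$control_replicates, design$include_t0) },
      interval = { dsn <- assay_design(design$observation_time, v, design$dose_series,
                                       design$control_replicates, design$include_t0) },
      tracer_conc = { trc <- tracer_spec(v, tracer$k1, tracer$k2) },
      tracer_k1 = { trc <- tracer_spec(tracer$L, v, tracer$k2) },
      tracer_k2 = { trc <- tracer_spec(tracer$L, tracer$k1, v) }
    )
    for (i in seq_len(nrow(compounds))) {
      cond <- cond + 1
      cp <- compound_spec(compounds$k3[i], compounds$k4[i])
      fits <- .mc_kpca_condition(trc, cp, dsn, noise, n_rep, seed, cond,
                                 fitter = fitter)
      sm <- summarize_mc(fits, list(k3 = cp$k3, k4 = cp$k4, KD2 = cp$KD2))
      out[[cond]] <- cbind(data.frame(axis = axis, value = v,
                                      k3_true = cp$k3, k4_true = cp$k4),
                           sm, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Apparent affinity vs incubation time (ePCA study)
#'
#' Simulates equilibrium probe competition assays at several incubation
#' times, fits each dose-response (one-site, Hill 1), converts the IC50 to
#' an apparent affinity via Cheng-Prusoff and compares it with the true
#' `KD2`. Finite incubation inflates the apparent KD of slowly equilibrating
#' compounds.
#'
#' @param compounds data.frame `k3`, `k4`; default 12-compound subset
#'   spanning slow-to-moderate off-rates.
#' @param incubation_times Incubation times \[s\] (default 1-24 h).
#' @param dose_series Compound doses \[M\] including 0.
#' @inheritParams run_rate_grid_study
#' @return A data.frame: per compound x time, apparent KD, true KD and their
#'   ratio (NA where the dose-response fit failed).
#' @export
run_epca_incubation_study <- function(compounds = expand.grid(k3 = 10^c(4, 6, 8),
                                                              k4 = 10^c(-5, -4, -3, -2)),
                                      tracer = standard_tracer(),
                                      incubation_times = c(1, 2, 4, 8, 16, 24) * 3600,
                                      dose_series = c(0, 10^seq(-13, -6, 0.5)),
                                      noise = noise_model(0), seed = 1) {
  out <- list(); cond <- 0
  for (i in seq_len(nrow(compounds))) {
    cp <- compound_spec(compounds$k3[i], compounds$k4[i])
    for (tt in incubation_times) {
      cond <- cond + 1
      dr <- simulate_epca(tracer, cp, tt, dose_series, noise,
                          seed = derive_seed(seed, cond))
      kd_app <- tryCatch({
        fit <- fit_dose_response(dr)
        cheng_prusoff(unname(fit$estimates["IC50"]), tracer$L, tracer$KD1)
      }, error = function(e) NA_real_)
      out[[cond]] <- data.frame(k3 = cp$k3, k4 = cp$k4, kd_true = cp$KD2,
                                incubation_s = tt, kd_apparent = kd_app,
                                ratio = kd_app / cp$KD2)
    }
  }
  do.call(rbind, out)
}

#' Error-signature study: systematic errors and wrong mechanisms
#'
#' Simulates competition association data under injected systematic errors
#' (wrong compound/tracer concentrations or tracer rates) or under
#' non-1:1 mechanisms (irreversible, induced fit), then evaluates them with
#' the plain reversible Motulsky-Mahan model using the NOMINAL parameters.
#' Reports accuracy of `k3`/`k4` per scenario and a residual-pattern
#' detection signal: the longest same-sign residual run, compared with the
#' 95th percentile of the unperturbed distribution.
#'
#' @param perturbations Named list of [perturbation_spec()] objects (and/or
#'   the strings `"irreversible"`, `"induced-fit"` for mechanism errors).
#' @param scenarios data.frame of exemplar compounds and designs; defaults
#'   to the slow (k4 = 1e-4, 1600 s / 10 s) and fast (k4 = 1e-2,
#'   400 s / 10 s) reference set-ups.
#' @inheritParams run_rate_grid_study
#' @return A data.frame: per scenario x perturbation, mean relative errors,
#'   median run statistic, baseline 95th percentile and a detection flag.
#' @export
run_error_signature_study <- function(perturbations = list(
                                        compound_conc_140 = perturbation_spec("compound_conc_all_wells", 1.4)),
                                      scenarios = data.frame(
                                        k3 = c(1e6, 1e6), k4 = c(1e-4, 1e-2),
                                        observation_time = c(1600, 400),
                                        interval = c(10, 10)),
                                      tracer = standard_tracer(),
                                      noise = noise_model(), n_rep = 100, seed = 1) {
  out <- list(); cond <- 0; row <- 0
  for (i in seq_len(nrow(scenarios))) {
    cp <- compound_spec(scenarios$k3[i], scenarios$k4[i])
    dsn <- assay_design(scenarios$observation_time[i], scenarios$interval[i])
    cond <- cond + 1
    base_fits <- .mc_kpca_condition(tracer, cp, dsn, noise, n_rep, seed, cond)
    base_tab <- .estimates_table(base_fits, data.frame(scenario = i))
    base_q95 <- stats::quantile(base_tab$run_stat, 0.95, na.rm = TRUE, names = FALSE)
    add_row <- function(label, fits, compound_true) {
      tab <- .estimates_table(fits, data.frame(scenario = i))
      conv <- tab[tab$converged, ]
      row <<- row + 1
      out[[row]] <<- data.frame(
        scenario = i, k3_true = compound_true$k3, k4_true = compound_true$k4,
        observation_time = dsn$observation_time, perturbation = label,
        n_converged = nrow(conv),
        rel_err_k3_pct = if (nrow(conv)) 100 * (compound_true$k3 - mean(conv$k3_hat)) / compound_true$k3 else NA,
        rel_err_k4_pct = if (nrow(conv) && compound_true$k4 > 0)
          100 * (compound_true$k4 - mean(conv$k4_hat)) / compound_true$k4 else NA,
        median_run_stat = stats::median(tab$run_stat, na.rm = TRUE),
        baseline_q95_run_stat = base_q95,
        frac_above_baseline = mean(tab$run_stat > base_q95, na.rm = TRUE),
        detected = stats::median(tab$run_stat, na.rm = TRUE) > base_q95,
        stringsAsFactors = FALSE)
    }
    add_row("none", base_fits, cp)
    for (j in seq_along(perturbations)) {
      pert <- perturbations[[j]]
      label <- if (!is.null(names(perturbations)) && nzchar(names(perturbations)[j]))
        names(perturbations)[j] else paste0("perturbation_", j)
      cond <- cond + 1
      if (is.character(pert)) {  # mechanism error, evaluated as reversible
        cp_mech <- compound_spec(cp$k3, if (pert == "irreversible") 0 else cp$k4,
                                 mechanism = pert)
        fits <- .mc_kpca_condition(tracer, cp_mech, dsn, noise, n_rep, seed, cond)
        add_row(pert, fits, cp_mech)
      } else {
        fits <- .mc_kpca_condition(tracer, cp, dsn, noise, n_rep, seed, cond,
                                   perturbation = pert)
        add_row(label, fits, cp)
      }
    }
  }
  do.call(rbind, out)
}

#' Tracer characterisation method comparison
#'
#' Monte Carlo comparison of the two tracer characterisation designs —
#' plain kinetic association versus association-then-dissociation (chase) —
#' over a grid of hypothetical tracers, reporting precision/accuracy of
#' `kon` and `koff` per tracer and method.
#'
#' @param tracers data.frame with columns `kon`, `koff`.
#' @param L_series Tracer concentrations \[M\] used on the plate.
#' @param design An [assay_design()] providing the time grid.
#' @param t_chase Chase time \[s\] for the chase design.
#' @inheritParams run_rate_grid_study
#' @return A data.frame: per tracer x method x parameter summary.
#' @export
run_tracer_method_comparison <- function(tracers = expand.grid(kon = 10^c(5, 6, 7),
                                                               koff = 10^c(-5, -3, -1)),
                                         L_series = c(3.125e-9, 12.5e-9, 50e-9),
                                         design = assay_design(1200, 10),
                                         t_chase = 600,
                                         noise = noise_model(), n_rep = 100,
                                         seed = 1) {
  out <- list(); cond <- 0; row <- 0
  for (i in seq_len(nrow(tracers))) {
    kon <- tracers$kon[i]; koff <- tracers$koff[i]
    for (mode in c("association", "association_then_dissociation")) {
      cond <- cond + 1
      fits <- vector("list", n_rep)
      for (r in seq_len(n_rep)) {
        seed_r <- derive_seed(seed, (cond - 1) * .mc_counter + r)
        fits[[r]] <- tryCatch({
          ts <- simulate_tracer_plate(mode, kon, koff, L_series,
                                      t_chase = if (mode == "association") NULL else t_chase,
                                      design = design, noise = noise, seed = seed_r)
          if (mode == "association") fit_association_global(ts)
          else fit_assoc_then_dissoc_global(ts, t_chase)
        }, error = function(e) e)
      }
      sm <- tryCatch(summarize_mc(fits, list(kon = kon, koff = koff, KD = koff / kon)),
                     error = function(e) NULL)
      if (!is.null(sm)) {
        row <- row + 1
        out[[row]] <- cbind(data.frame(kon_true = kon, koff_true = koff,
                                       method = mode), sm, row.names = NULL)
      }
    }
  }
  do.call(rbind, out)
}
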