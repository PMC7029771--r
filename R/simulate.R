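#' Assay design
#'
#' Time schedule, dose series and control layout of a kinetic probe
#' competition assay (kPCA) plate.
#'
#' @param observation_time Total measurement time \[s\].
#' @param interval Measuring interval \[s\]; the time grid is
#'   `interval, 2*interval, ..., <= observation_time` (optionally with t = 0
#'   prepended).
#' @param dose_series Compound concentrations \[M\]; must contain 0 (the
#'   vehicle control). Default brackets a 250 nM mid dose with a 10-fold
#'   series.
#' @param control_replicates Number of vehicle (100% tracer binding) and
#'   background (0%) control wells, used for normalisation and Z'-factor
#'   estimation.
#' @param include_t0 Prepend t = 0 to the time grid?
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(400, 10)
#' @export
assay_design <- function(observation_time = 400, interval = 10,
                         dose_series = c(0, 2.5e-9, 25e-9, 250e-9, 2500e-9),
                         control_replicates = 3, include_t0 = FALSE) {
  check_finite_scalar(observation_time, "design.observation_time", min = 0, strict = TRUE)
  check_finite_scalar(interval, "design.interval", min = 0, strict = TRUE)
  if (interval > observation_time) {
    stop("invalid design: 'design.interval' exceeds 'design.observation_time'",
         call. = FALSE)
  }
  if (!is.numeric(dose_series) || any(!is.finite(dose_series)) || any(dose_series < 0)) {
    stop("'design.dose_series' must be non-negative finite concentrations [M]",
         call. = FALSE)
  }
  if (!any(dose_series == 0)) {
    stop("'design.dose_series' must contain 0 (the vehicle control)", call. = FALSE)
  }
  check_finite_scalar(control_replicates, "design.control_replicates", min = 1, strict = FALSE)
  structure(list(observation_time = observation_time, interval = interval,
                 dose_series = sort(unique(dose_series)),
                 control_replicates = as.integer(control_replicates),
                 include_t0 = isTRUE(include_t0)),
            class = "assay_design")
}

#' Noise model
#'
#' Additive Gaussian, homoscedastic measurement noise: the same SD for all
#' wells and time points, expressed as a fraction of the assay window (the
#' vehicle-control equilibrium signal minus background).
#'
#' @param sd_fraction Noise SD as a fraction of the assay window; default
#'   0.01 (1%).
#' @param seed Optional RNG seed for reproducible simulation.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_fraction = 0.01, seed = NULL) {
  check_finite_scalar(sd_fraction, "noise.sd_fraction", min = 0, strict = FALSE)
  if (!is.null(seed)) check_finite_scalar(seed, "noise.seed")
  structure(list(sd_fraction = sd_fraction, seed = seed), class = "noise_model")
}

#' Systematic-error (perturbation) specification
#'
#' Injects a multiplicative discrepancy between the parameters used to
#' GENERATE the data and the nominal parameters later used to EVALUATE them,
#' emulating pipetting/characterisation errors.
#'
#' @param kind One of `"compound_conc_all_wells"`, `"compound_conc_single_well"`,
#'   `"tracer_conc"`, `"tracer_k1"`, `"tracer_k2"`.
#' @param factor Multiplicative error, > 0 (e.g. 1.4 = +40%).
#' @param target_dose_index For the single-well kind: index into the nonzero
#'   dose series (default: the dose closest to 250 nM).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("compound_conc_all_wells",
                                       "compound_conc_single_well",
                                       "tracer_conc", "tracer_k1", "tracer_k2"),
                              factor, target_dose_index = NULL) {
  kind <- match.arg(kind)
  check_finite_scalar(factor, "perturbation.factor", min = 0, strict = TRUE)
  structure(list(kind = kind, factor = factor,
                 target_dose_index = target_dose_index),
            class = "perturbation_spec")
}

#' Time grid of an assay design
#'
#' @param design An [assay_design()].
#' @return Numeric vector of measurement times \[s\].
#' @examples
#' build_time_grid(assay_design(400, 10))
#' @export
build_time_grid <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  n <- floor(design$observation_time / design$interval + 1e-9)
  grid <- design$interval * seq_len(n)
  if (design$include_t0) grid <- c(0, grid)
  grid
}

# --- seeding -----------------------------------------------------------------

#' Derive a replicate sub-seed from a master seed
#'
#' Stable counter-based substream derivation: replicate r of a study always
#' receives the same seed for a given master seed, regardless of how many
#' replicates are run in total.
#'
#' @param master Master seed (integer).
#' @param counter Replicate/condition counter (integer >= 0).
#' @return An integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, counter) {
  m <- as.numeric(master) %% 2147483647
  x <- (m * 48271 + as.numeric(counter) * 16807 + 12345) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# --- trace sets --------------------------------------------------------------

new_trace_set <- function(data, state = c("raw", "normalised"), metadata = list()) {
  state <- match.arg(state)
  stopifnot(is.data.frame(data),
            all(c("trace_id", "role", "dose_M", "time_s", "signal") %in% names(data)))
  structure(list(data = data, state = state, metadata = metadata),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  ids <- unique(x$data$trace_id)
  cat(sprintf("<trace_set: %s> %d traces x %d time points (%g..%g s)\n",
              x$state, length(ids), length(unique(x$data$time_s)),
              min(x$data$time_s), max(x$data$time_s)))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$data$role[!duplicated(x$data$trace_id)])),
                              table(x$data$role[!duplicated(x$data$trace_id)])), collapse = ", "), "\n")
  invisible(x)
}

trace_times <- function(ts) sort(unique(ts$data$time_s))

trace_signal <- function(ts, id) {
  d <- ts$data[ts$data$trace_id == id, ]
  d$signal[order(d$time_s)]
}

# mean control trace by role, over replicate wells, per time point
control_mean <- function(ts, role) {
  d <- ts$data[ts$data$role == role, ]
  if (nrow(d) == 0) return(NULL)
  out <- tapply(d$signal, d$time_s, mean)
  as.numeric(out[order(as.numeric(names(out)))])
}

# --- kPCA simulator ----------------------------------------------------------

#' Simulate a kinetic probe competition assay (kPCA) plate
#'
#' Generates raw competition association traces for every compound dose, plus
#' replicated vehicle (tracer-only) and background (no tracer binding)
#' control wells, with additive Gaussian noise. Data are generated from the
#' TRUE parameters (after any injected perturbation); the nominal parameters
#' are recorded in the metadata so that downstream fits reproduce the
#' evaluate-with-wrong-inputs scenario.
#'
#' @param design An [assay_design()].
#' @param tracer A [tracer_spec()] (nominal).
#' @param compound A [compound_spec()].
#' @param noise A [noise_model()].
#' @param perturbation Optional [perturbation_spec()].
#' @param amplitude An [amplitude_params()] for the raw signal scale.
#' @param seed RNG seed; defaults to `noise$seed`.
#' @return A raw `trace_set`. Metadata records times, nominal and true
#'   parameters, the noise SD and the seed.
#' @export
simulate_kpca <- function(design, tracer, compound, noise = noise_model(),
                          perturbation = NULL,
                          amplitude = amplitude_params(), seed = noise$seed) {
  stopifnot(inherits(design, "assay_design"))
  tracer <- as_tracer(tracer); compound <- as_compound(compound)
  times <- build_time_grid(design)
  doses <- setdiff(design$dose_series, 0)

  true_tracer <- tracer
  true_doses <- doses
  if (!is.null(perturbation)) {
    stopifnot(inherits(perturbation, "perturbation_spec"))
    f <- perturbation$factor
    switch(perturbation$kind,
      compound_conc_all_wells = { true_doses <- doses * f },
      compound_conc_single_well = {
        idx <- perturbation$target_dose_index
        if (is.null(idx)) idx <- which.min(abs(doses - 250e-9))
        true_doses[idx] <- doses[idx] * f
      },
      tracer_conc = { true_tracer <- tracer_spec(tracer$L * f, tracer$k1, tracer$k2) },
      tracer_k1 = { true_tracer <- tracer_spec(tracer$L, tracer$k1 * f, tracer$k2) },
      tracer_k2 = { true_tracer <- tracer_spec(tracer$L, tracer$k1, tracer$k2 * f) }
    )
  }

  # assay window: vehicle-control equilibrium signal minus background
  window <- amplitude$Bmax * true_tracer$L / (true_tracer$L + true_tracer$KD1)
  sd_abs <- noise$sd_fraction * window

  model_trace <- function(I) {
    if (compound$mechanism == "reversible" || I == 0) {
      specific_binding_trace(times, true_tracer, compound, I, amplitude)
    } else {
      mechanism_ode_trace(times, true_tracer, compound, I, amplitude)
    }
  }

  rows <- list()
  add <- function(id, role, dose, signal) {
    rows[[length(rows) + 1L]] <<- data.frame(
      trace_id = id, role = role, dose_M = dose, time_s = times,
      signal = signal, stringsAsFactors = FALSE)
  }
  for (j in seq_along(doses)) {
    add(sprintf("dose_%02d", j), "dose", doses[j], model_trace(true_doses[j]))
  }
  veh <- model_trace(0)
  bg <- rep(amplitude$y0, length(times))
  for (r in seq_len(design$control_replicates)) {
    add(sprintf("vehicle_%02d", r), "vehicle", 0, veh)
    add(sprintf("background_%02d", r), "background", NA_real_, bg)
  }
  data <- do.call(rbind, rows)
  if (sd_abs > 0) {
    data$signal <- with_seed(seed, data$signal + stats::rnorm(nrow(data), 0, sd_abs))
  }
  new_trace_set(data, "raw", metadata = list(
    times = times, design = design, amplitude = amplitude,
    tracer_nominal = tracer, tracer_true = true_tracer,
    compound = compound, doses_nominal = doses, doses_true = true_doses,
    noise_sd = sd_abs, sd_fraction = noise$sd_fraction, seed = seed,
    perturbation = perturbation))
}

#' Normalise a raw trace set to percent compound binding
#'
#' Per-time-point normalisation against the plate's own controls:
#' \deqn{\hat y(t) = 100\,(1 - (y(t) - bg(t)) / (veh(t) - bg(t)))}
#' where `veh` and `bg` are the time-point-wise means of the vehicle and
#' background control wells. Any multiplicative drift shared by all wells
#' cancels in the ratio. Normalising an already-normalised set is an error.
#'
#' @param ts A raw `trace_set` containing vehicle and background controls.
#' @return A normalised `trace_set` (dose traces only; controls are consumed
#'   by the normalisation).
#' @export
normalize_traces <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  if (ts$state != "raw") {
    stop("trace set is already normalised; refusing to re-normalise", call. = FALSE)
  }
  veh <- control_mean(ts, "vehicle")
  bg <- control_mean(ts, "background")
  if (is.null(veh) || is.null(bg)) {
    stop("normalisation requires vehicle and background control traces", call. = FALSE)
  }
  win <- veh - bg
  if (any(win <= 0)) {
    stop("degenerate assay window: vehicle - background <= 0 at some time point",
         call. = FALSE)
  }
  times <- trace_times(ts)
  d <- ts$data[ts$data$role == "dose", ]
  d <- d[order(d$trace_id, d$time_s), ]
  idx <- match(d$time_s, times)
  d$signal <- 100 * (1 - (d$signal - bg[idx]) / win[idx])
  meta <- ts$metadata
  meta$normalisation <- list(vehicle = as.numeric(veh), background = as.numeric(bg))
  new_trace_set(d, "normalised", metadata = meta)
}

#' Simulate an equilibrium probe competition assay (ePCA)
#'
#' Endpoint dose-response: percent tracer binding at a single incubation time
#' per compound dose, normalised to the plate's vehicle and background
#' signals. With a finite incubation time the response is the kinetic
#' competition model evaluated at that time, so slowly equilibrating
#' compounds produce right-shifted (apparently weaker) curves.
#'
#' @inheritParams simulate_kpca
#' @param incubation_time Incubation time \[s\], > 0.
#' @param dose_series Compound concentrations \[M\] including 0.
#' @return A `dose_response` data.frame with columns `dose_M` and
#'   `response_pct` (percent tracer binding).
#' @export
simulate_epca <- function(tracer, compound, incubation_time,
                          dose_series = c(0, 10^seq(-13, -6, 0.5)),
                          noise = noise_model(), amplitude = amplitude_params(),
                          seed = noise$seed) {
  tracer <- as_tracer(tracer); compound <- as_compound(compound)
  check_finite_scalar(incubation_time, "incubation_time", min = 0, strict = TRUE)
  doses <- sort(unique(dose_series))
  raw <- vapply(doses, function(I) {
    if (compound$mechanism == "reversible" || I == 0) {
      specific_binding_trace(incubation_time, tracer, compound, I, amplitude)
    } else {
      mechanism_ode_trace(incubation_time, tracer, compound, I, amplitude)
    }
  }, numeric(1))
  veh <- specific_binding_trace(incubation_time, tracer, compound, 0, amplitude)
  bg <- amplitude$y0
  window <- amplitude$Bmax * tracer$L / (tracer$L + tracer$KD1)
  sd_abs <- noise$sd_fraction * window
  if (sd_abs > 0) {
    noisy <- with_seed(seed, {
      list(raw = raw + stats::rnorm(length(raw), 0, sd_abs),
           veh = veh + stats::rnorm(1, 0, sd_abs),
           bg = bg + stats::rnorm(1, 0, sd_abs))
    })
    raw <- noisy$raw; veh <- noisy$veh; bg <- noisy$bg
  }
  out <- data.frame(dose_M = doses,
                    response_pct = 100 * (raw - bg) / (veh - bg))
  attr(out, "incubation_time") <- incubation_time
  attr(out, "tracer") <- tracer
  attr(out, "compound") <- compound
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Simulate a tracer characterisation plate
#'
#' Direct tracer binding at several tracer concentrations, either plain
#' association or association followed by displacement with excess unlabelled
#' tracer ("chase") within the same wells.
#'
#' @param mode `"association"` or `"association_then_dissociation"`.
#' @param kon,koff Tracer rate constants.
#' @param L_series Tracer concentrations \[M\] (>= 3 recommended for global
#'   fitting).
#' @param t_chase Chase time \[s\] (chase mode only; must lie inside the
#'   observation window).
#' @param design An [assay_design()] providing the time grid; its dose series
#'   is ignored.
#' @inheritParams simulate_kpca
#' @param Bmax,y0 Amplitude parameters of the raw signal.
#' @return A raw `trace_set` whose dose traces carry the tracer
#'   concentrations in `dose_M`.
#' @export
simulate_tracer_plate <- function(mode = c("association", "association_then_dissociation"),
                                  kon, koff, L_series, t_chase = NULL,
                                  design = assay_design(), noise = noise_model(),
                                  Bmax = 1, y0 = 0, seed = noise$seed) {
  mode <- match.arg(mode)
  if (length(L_series) < 1 || any(L_series <= 0)) {
    stop("'L_series' must be positive tracer concentrations [M]", call. = FALSE)
  }
  times <- build_time_grid(design)
  if (mode == "association_then_dissociation") {
    if (is.null(t_chase) || t_chase <= 0 || t_chase >= design$observation_time) {
      stop("invalid design: 't_chase' must lie inside the observation window",
           call. = FALSE)
    }
  }
  rows <- list()
  for (j in seq_along(L_series)) {
    L <- L_series[j]
    sig <- if (mode == "association") {
      mono_association_trace(times, L, kon, koff, Bmax, y0)
    } else {
      association_then_dissociation_trace(times, t_chase, L, kon, koff, Bmax, y0)
    }
    rows[[j]] <- data.frame(trace_id = sprintf("L_%02d", j), role = "dose",
                            dose_M = L, time_s = times, signal = sig,
                            stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    trace_id = "background_01", role = "background", dose_M = NA_real_,
    time_s = times, signal = rep(y0, length(times)), stringsAsFactors = FALSE)
  data <- do.call(rbind, rows)
  KD <- koff / kon
  window <- Bmax * max(L_series) / (max(L_series) + KD)
  sd_abs <- noise$sd_fraction * window
  if (sd_abs > 0) {
    data$signal <- with_seed(seed, data$signal + stats::rnorm(nrow(data), 0, sd_abs))
  }
  new_trace_set(data, "raw", metadata = list(
    times = times, mode = mode, kon = kon, koff = koff, L_series = L_series,
    t_chase = t_chase, Bmax = Bmax, y0 = y0, noise_sd = sd_abs, seed = seed))
}
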