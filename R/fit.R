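# Global nonlinear least-squares fitters for competition association data.
#
# All fitters share one engine: rate constants are fitted as log10 values
# (positivity + scale invariance over many decades), amplitude-like
# parameters (y0, Bmax, top/bottom) enter the models linearly and are solved
# exactly by linear least squares inside the residual callback (variable
# projection), and the nonlinear search is a deterministic multi-start
# Levenberg-Marquardt (minpack.lm::nls.lm) over a fixed log-spaced grid.

.LOG_KON_BOUNDS <- c(2, 11)
.LOG_KOFF_BOUNDS <- c(-8, 2)

# fast fractional occupancy, no spec-object overhead; KS from the product
# identity KF*KS = k1*L*k4 + k2*k3*I + k2*k4 for numerical stability
.mm_occ_fast <- function(times, k1, L, k2, k3, I, k4) {
  KA <- k1 * L + k2
  if (I == 0) {
    return((k1 * L / KA) * (1 - exp(-KA * times)))
  }
  KB <- k3 * I + k4
  disc <- sqrt((KA - KB)^2 + 4 * k1 * k3 * L * I)
  KF <- 0.5 * (KA + KB + disc)
  KS <- (k1 * L * k4 + k2 * k3 * I + k2 * k4) / KF
  if (KF - KS < 1e-10 * KF) KS <- KS - 1e-8 * KF
  Diff <- KF - KS
  bracket <- k4 * Diff / (KF * KS) +
    ((k4 - KF) / KF) * exp(-KF * times) -
    ((k4 - KS) / KS) * exp(-KS * times)
  (k1 * L / Diff) * bracket
}

.mm_norm_fast <- function(times, k1, L, k2, k3, I, k4) {
  KA <- k1 * L + k2
  if (I == 0) return(numeric(length(times)))
  KB <- k3 * I + k4
  disc <- sqrt((KA - KB)^2 + 4 * k1 * k3 * L * I)
  KF <- 0.5 * (KA + KB + disc)
  KS <- (k1 * L * k4 + k2 * k3 * I + k2 * k4) / KF
  if (KF - KS < 1e-10 * KF) KS <- KS - 1e-8 * KF
  Diff <- KF - KS
  out <- numeric(length(times))
  pos <- times > 0
  t <- times[pos]
  bracket <- k4 * Diff / (KF * KS) +
    ((k4 - KF) / KF) * exp(-KF * t) -
    ((k4 - KS) / KS) * exp(-KS * t)
  out[pos] <- 100 * (1 - (KA / (Diff * (1 - exp(-KA * t)))) * bracket)
  out
}

# --- engine ------------------------------------------------------------------

# model_fun(theta) must return either
#   a numeric vector (pure nonlinear model), or
#   a matrix X of linear basis columns; beta is then solved from y ~ X.
# Returns best start: list(theta, beta, fitted, sse, converged, start_sse).
.multistart_fit <- function(y, model_fun, starts, lower, upper,
                            linear = TRUE, tie_dim = NULL, maxiter = 60) {
  eval_theta <- function(theta) {
    m <- model_fun(theta)
    if (linear) {
      X <- m
      beta <- tryCatch(qr.solve(qr(X, LAPACK = TRUE), y),
                       error = function(e) {
                         s <- svd(X)
                         keep <- s$d > max(s$d) * 1e-12
                         drop(s$v[, keep, drop = FALSE] %*%
                                ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep]))
                       })
      fitted <- drop(X %*% beta)
      list(resid = y - fitted, beta = beta, fitted = fitted)
    } else {
      list(resid = y - m, beta = numeric(0), fitted = m)
    }
  }
  results <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lower, upper = upper,
                         fn = function(th) eval_theta(th)$resid,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) {
      results[[s]] <- list(theta = starts[s, ], sse = Inf, converged = FALSE)
    } else {
      results[[s]] <- list(theta = fit$par, sse = fit$deviance,
                           converged = fit$info %in% 1:4)
    }
  }
  sses <- vapply(results, `[[`, numeric(1), "sse")
  conv <- vapply(results, `[[`, logical(1), "converged")
  if (!any(conv)) {
    best <- which.min(sses)
    cond <- structure(
      class = c("kinbind_nonconvergence", "error", "condition"),
      list(message = "no multi-start fit converged",
           call = sys.call(-1),
           diagnostics = list(start_sse = sses,
                              best_theta = results[[best]]$theta)))
    stop(cond)
  }
  cand <- which(conv)
  best_sse <- min(sses[cand])
  near <- cand[sses[cand] <= best_sse * (1 + 1e-9)]
  best <- if (length(near) > 1L && !is.null(tie_dim)) {
    near[which.min(vapply(near, function(i) results[[i]]$theta[tie_dim], numeric(1)))]
  } else {
    near[which.min(sses[near])]
  }
  theta <- results[[best]]$theta
  ev <- eval_theta(theta)
  list(theta = theta, beta = ev$beta, fitted = ev$fitted,
       resid = ev$resid, sse = sum(ev$resid^2), converged = TRUE,
       start_sse = sses, n_starts = nrow(starts))
}

# Unit-noise covariance of the full parameter vector from a numerical
# Jacobian of the fitted model. Reported standard errors use the observed
# residual SD; the ill-determinedness flag is evaluated at a noise floor of
# 1% of the signal spread (the nominal assay noise), so that parameters
# whose profile is flat relative to realistic noise are flagged even on
# noise-free data. Returns NULL if the normal matrix is singular.
.fit_covariance <- function(full_model, p, y) {
  n <- length(y); np <- length(p)
  J <- matrix(0, n, np)
  f0 <- full_model(p)
  for (j in seq_len(np)) {
    h <- max(1e-5, abs(p[j]) * 1e-5)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    J[, j] <- (full_model(pp) - full_model(pm)) / (2 * h)
  }
  V_unit <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  if (is.null(V_unit)) return(NULL)
  sse <- sum((y - f0)^2)
  sigma_hat <- sqrt(sse / max(n - np, 1))
  sigma_floor <- max(sigma_hat, 0.01 * stats::sd(y))
  list(V = sigma_hat^2 * V_unit, V_ill = sigma_floor^2 * V_unit)
}

.cov_se <- function(cv) {
  if (is.null(cv)) return(NULL)
  list(se = sqrt(pmax(diag(cv$V), 0)), se_ill = sqrt(pmax(diag(cv$V_ill), 0)))
}

.cov_se_diff <- function(cv, i, j) {
  # SE of p[j] - p[i] (log10 KD = log10 k4 - log10 k3)
  if (is.null(cv)) return(c(NA_real_, NA_real_))
  c(sqrt(max(cv$V[i, i] + cv$V[j, j] - 2 * cv$V[i, j], 0)),
    sqrt(max(cv$V_ill[i, i] + cv$V_ill[j, j] - 2 * cv$V_ill[i, j], 0)))
}

.rate_param_row <- function(name, log10_val, se_log10, se_ill = se_log10) {
  # flagged when the 95% CI (at the noise floor) spans more than 2 decades
  ill <- !is.finite(se_ill) || 2 * 1.96 * se_ill > 2
  data.frame(parameter = name, estimate = 10^log10_val,
             se = se_log10, scale = "log10",
             ci_lo = if (is.finite(se_log10)) 10^(log10_val - 1.96 * se_log10) else NA_real_,
             ci_hi = if (is.finite(se_log10)) 10^(log10_val + 1.96 * se_log10) else NA_real_,
             ill_determined = ill, stringsAsFactors = FALSE)
}

.linear_param_row <- function(name, val, se) {
  data.frame(parameter = name, estimate = val, se = se, scale = "linear",
             ci_lo = if (is.finite(se)) val - 1.96 * se else NA_real_,
             ci_hi = if (is.finite(se)) val + 1.96 * se else NA_real_,
             ill_determined = NA, stringsAsFactors = FALSE)
}

new_fit_result <- function(params, sse, n_points, n_starts, residual_table = NULL,
                           extra = list()) {
  est <- stats::setNames(params$estimate, params$parameter)
  ill <- stats::setNames(params$ill_determined, params$parameter)
  structure(c(list(estimates = est, parameters = params,
                   ill_determined = ill, sse = sse, converged = TRUE,
                   n_points = n_points, n_starts_used = n_starts,
                   residuals = residual_table), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> converged = %s, SSE = %.6g, n = %d (%d starts)\n",
              x$converged, x$sse, x$n_points, x$n_starts_used))
  print(x$parameters, row.names = FALSE, digits = 4)
  invisible(x)
}

.theta_grid_rates <- function(extra = NULL) {
  l3 <- seq(3, 10, length.out = 5)
  l4 <- seq(-7, 1, length.out = 5)
  g <- as.matrix(expand.grid(l3, l4))
  colnames(g) <- NULL
  if (!is.null(extra)) g <- cbind(g, matrix(rep(extra, each = nrow(g)), nrow = nrow(g)))
  g
}

# assemble kinetic fitting frame from a trace set (dose + vehicle roles),
# t = 0 points excluded (the normalised model is defined piecewise there)
.kinetic_frame <- function(ts, roles = c("dose", "vehicle")) {
  d <- ts$data[ts$data$role %in% roles & ts$data$time_s > 0, ]
  d[order(d$trace_id, d$time_s), ]
}

# --- kPCA fitters ------------------------------------------------------------

#' Global Motulsky-Mahan fit of raw competition association traces
#'
#' Fits all dose traces (and vehicle control wells) of a raw trace set
#' simultaneously to the raw-signal competition association model with
#' shared parameters `k3`, `k4`, `Bmax`, `y0`. `k3`/`k4` are fitted as log10
#' values over a deterministic 5x5 multi-start grid; `Bmax` and `y0` are
#' profiled out by linear least squares at every step. Tracer parameters and
#' doses are fixed to their nominal values.
#'
#' A parameter is flagged `ill_determined` when its 95% confidence interval
#' (from the covariance at the optimum, in log10 space) spans more than two
#' decades — the fit "drifting" regime where only the complementary
#' parameter combination is identified.
#'
#' @param ts A raw `trace_set` from [simulate_kpca()] or [read_traces()].
#' @param tracer Nominal [tracer_spec()]; defaults to the one recorded in
#'   the trace-set metadata.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `fit_result` with estimates for `k3`, `k4`, `KD2`, `Bmax`, `y0`.
#' @export
fit_kpca_global <- function(ts, tracer = NULL, maxiter = 60) {
  stopifnot(inherits(ts, "trace_set"))
  if (ts$state != "raw") stop("fit_kpca_global expects a raw trace set", call. = FALSE)
  if (is.null(tracer)) tracer <- ts$metadata$tracer_nominal
  tracer <- as_tracer(tracer)
  d <- .kinetic_frame(ts)
  d$dose_M[is.na(d$dose_M)] <- 0
  doses <- unique(d$dose_M[d$role == "dose"])
  if (length(doses[doses > 0]) < 2) {
    stop("invalid data: need >= 2 nonzero dose traces for a global fit", call. = FALSE)
  }
  groups <- split(seq_len(nrow(d)), d$trace_id)
  y <- d$signal
  k1 <- tracer$k1; L <- tracer$L; k2 <- tracer$k2

  basis <- function(theta) {
    f <- numeric(nrow(d))
    for (g in groups) {
      f[g] <- .mm_occ_fast(d$time_s[g], k1, L, k2,
                           10^theta[1], d$dose_M[g][1], 10^theta[2])
    }
    cbind(1, f)
  }
  best <- .multistart_fit(y, basis, .theta_grid_rates(),
                          lower = c(.LOG_KON_BOUNDS[1], .LOG_KOFF_BOUNDS[1]),
                          upper = c(.LOG_KON_BOUNDS[2], .LOG_KOFF_BOUNDS[2]),
                          tie_dim = 2, maxiter = maxiter)
  p <- c(best$theta, best$beta)  # l3, l4, y0, Bmax
  full_model <- function(pp) {
    X <- basis(pp[1:2]); drop(X %*% pp[3:4])
  }
  cv <- .fit_covariance(full_model, p, y)
  s <- .cov_se(cv)
  se <- if (is.null(s)) rep(NA_real_, 4) else s$se
  sei <- if (is.null(s)) rep(NA_real_, 4) else s$se_ill
  kd <- .cov_se_diff(cv, 1, 2)
  params <- rbind(.rate_param_row("k3", p[1], se[1], sei[1]),
                  .rate_param_row("k4", p[2], se[2], sei[2]),
                  .rate_param_row("KD2", p[2] - p[1], kd[1], kd[2]),
                  .linear_param_row("y0", p[3], se[3]),
                  .linear_param_row("Bmax", p[4], se[4]))
  resid_tab <- data.frame(trace_id = d$trace_id, dose_M = d$dose_M,
                          time_s = d$time_s, fitted = best$fitted,
                          resid = best$resid, stringsAsFactors = FALSE)
  new_fit_result(params, best$sse, length(y), best$n_starts, resid_tab)
}

#' Global fit of normalised competition traces
#'
#' Fits the normalised (amplitude-free) competition association model to
#' percent-compound-binding traces with only `k3`, `k4` free. t = 0 points
#' are excluded (the model is 0 there by definition). Because the model has
#' no `Bmax`, common multiplicative signal drift has already cancelled in
#' the normalisation and does not bias the estimates.
#'
#' @inheritParams fit_kpca_global
#' @param ts A normalised `trace_set` from [normalize_traces()].
#' @return A `fit_result` with `k3`, `k4`, `KD2`.
#' @export
fit_kpca_normalized <- function(ts, tracer = NULL, maxiter = 60) {
  stopifnot(inherits(ts, "trace_set"))
  if (ts$state != "normalised") {
    stop("fit_kpca_normalized expects a normalised trace set", call. = FALSE)
  }
  if (is.null(tracer)) tracer <- ts$metadata$tracer_nominal
  tracer <- as_tracer(tracer)
  d <- .kinetic_frame(ts, roles = "dose")
  d <- d[d$dose_M > 0, ]
  if (nrow(d) == 0 || length(unique(d$dose_M)) < 1) {
    stop("invalid data: no nonzero-dose normalised traces to fit", call. = FALSE)
  }
  groups <- split(seq_len(nrow(d)), d$trace_id)
  y <- d$signal
  k1 <- tracer$k1; L <- tracer$L; k2 <- tracer$k2
  model <- function(theta) {
    f <- numeric(nrow(d))
    for (g in groups) {
      f[g] <- .mm_norm_fast(d$time_s[g], k1, L, k2,
                            10^theta[1], d$dose_M[g][1], 10^theta[2])
    }
    f
  }
  best <- .multistart_fit(y, model, .theta_grid_rates(),
                          lower = c(.LOG_KON_BOUNDS[1], .LOG_KOFF_BOUNDS[1]),
                          upper = c(.LOG_KON_BOUNDS[2], .LOG_KOFF_BOUNDS[2]),
                          linear = FALSE, tie_dim = 2, maxiter = maxiter)
  cv <- .fit_covariance(function(pp) model(pp), best$theta, y)
  s <- .cov_se(cv)
  se <- if (is.null(s)) rep(NA_real_, 2) else s$se
  sei <- if (is.null(s)) rep(NA_real_, 2) else s$se_ill
  kd <- .cov_se_diff(cv, 1, 2)
  params <- rbind(.rate_param_row("k3", best$theta[1], se[1], sei[1]),
                  .rate_param_row("k4", best$theta[2], se[2], sei[2]),
                  .rate_param_row("KD2", best$theta[2] - best$theta[1], kd[1], kd[2]))
  resid_tab <- data.frame(trace_id = d$trace_id, dose_M = d$dose_M,
                          time_s = d$time_s, fitted = best$fitted,
                          resid = best$resid, stringsAsFactors = FALSE)
  new_fit_result(params, best$sse, length(y), best$n_starts, resid_tab)
}

#' Global Motulsky-Mahan fit with a multiplicative signal-drift term
#'
#' As [fit_kpca_global()], but the background-subtracted specific signal is
#' multiplied by `exp(-KDrift * t)` to absorb binding-independent signal
#' decay (photobleaching and similar). Shared `k3`, `k4`, `KDrift`, `Bmax`,
#' `y0`; `KDrift >= 0` enforced.
#'
#' @inheritParams fit_kpca_global
#' @return A `fit_result` including `KDrift`.
#' @export
fit_kpca_drift <- function(ts, tracer = NULL, maxiter = 60) {
  stopifnot(inherits(ts, "trace_set"))
  if (ts$state != "raw") stop("fit_kpca_drift expects a raw trace set", call. = FALSE)
  if (is.null(tracer)) tracer <- ts$metadata$tracer_nominal
  tracer <- as_tracer(tracer)
  d <- .kinetic_frame(ts)
  d$dose_M[is.na(d$dose_M)] <- 0
  groups <- split(seq_len(nrow(d)), d$trace_id)
  y <- d$signal
  k1 <- tracer$k1; L <- tracer$L; k2 <- tracer$k2
  basis <- function(theta) {
    f <- numeric(nrow(d))
    for (g in groups) {
      f[g] <- .mm_occ_fast(d$time_s[g], k1, L, k2,
                           10^theta[1], d$dose_M[g][1], 10^theta[2]) *
        exp(-theta[3] * d$time_s[g])
    }
    cbind(1, f)
  }
  best <- .multistart_fit(y, basis, .theta_grid_rates(extra = 1e-3),
                          lower = c(.LOG_KON_BOUNDS[1], .LOG_KOFF_BOUNDS[1], 0),
                          upper = c(.LOG_KON_BOUNDS[2], .LOG_KOFF_BOUNDS[2], 0.1),
                          tie_dim = 2, maxiter = maxiter)
  p <- c(best$theta, best$beta)  # l3, l4, KDrift, y0, Bmax
  full_model <- function(pp) drop(basis(pp[1:3]) %*% pp[4:5])
  cv <- .fit_covariance(full_model, p, y)
  s <- .cov_se(cv)
  se <- if (is.null(s)) rep(NA_real_, 5) else s$se
  sei <- if (is.null(s)) rep(NA_real_, 5) else s$se_ill
  kd <- .cov_se_diff(cv, 1, 2)
  params <- rbind(.rate_param_row("k3", p[1], se[1], sei[1]),
                  .rate_param_row("k4", p[2], se[2], sei[2]),
                  .rate_param_row("KD2", p[2] - p[1], kd[1], kd[2]),
                  .linear_param_row("KDrift", p[3], se[3]),
                  .linear_param_row("y0", p[4], se[4]),
                  .linear_param_row("Bmax", p[5], se[5]))
  resid_tab <- data.frame(trace_id = d$trace_id, dose_M = d$dose_M,
                          time_s = d$time_s, fitted = best$fitted,
                          resid = best$resid, stringsAsFactors = FALSE)
  new_fit_result(params, best$sse, length(y), best$n_starts, resid_tab)
}

# --- tracer characterisation fitters ----------------------------------------

.fit_tracer_engine <- function(ts, model_of_L, maxiter = 60) {
  d <- .kinetic_frame(ts, roles = "dose")
  if (length(unique(d$dose_M)) < 3) {
    stop("invalid data: need >= 3 tracer concentrations for a global fit",
         call. = FALSE)
  }
  groups <- split(seq_len(nrow(d)), d$trace_id)
  y <- d$signal
  basis <- function(theta) {
    f <- numeric(nrow(d))
    for (g in groups) {
      f[g] <- model_of_L(d$time_s[g], d$dose_M[g][1], 10^theta[1], 10^theta[2])
    }
    cbind(f)
  }
  grid <- as.matrix(expand.grid(seq(3, 10, length.out = 5),
                                seq(-7, 1, length.out = 5)))
  colnames(grid) <- NULL
  best <- .multistart_fit(y, basis, grid,
                          lower = c(.LOG_KON_BOUNDS[1], .LOG_KOFF_BOUNDS[1]),
                          upper = c(.LOG_KON_BOUNDS[2], .LOG_KOFF_BOUNDS[2]),
                          tie_dim = 2, maxiter = maxiter)
  p <- c(best$theta, best$beta)  # lon, loff, Bmax
  full_model <- function(pp) drop(basis(pp[1:2]) %*% pp[3])
  cv <- .fit_covariance(full_model, p, y)
  s <- .cov_se(cv)
  se <- if (is.null(s)) rep(NA_real_, 3) else s$se
  sei <- if (is.null(s)) rep(NA_real_, 3) else s$se_ill
  kd <- .cov_se_diff(cv, 1, 2)
  params <- rbind(.rate_param_row("kon", p[1], se[1], sei[1]),
                  .rate_param_row("koff", p[2], se[2], sei[2]),
                  .rate_param_row("KD", p[2] - p[1], kd[1], kd[2]),
                  .linear_param_row("Bmax", p[3], se[3]))
  resid_tab <- data.frame(trace_id = d$trace_id, dose_M = d$dose_M,
                          time_s = d$time_s, fitted = best$fitted,
                          resid = best$resid, stringsAsFactors = FALSE)
  new_fit_result(params, best$sse, length(y), best$n_starts, resid_tab)
}

#' Global pseudo-first-order association fit across tracer concentrations
#'
#' Fits all tracer-concentration traces of an association plate to
#' `B(t) = Bmax (L/(L+KD)) (1 - exp(-(kon L + koff) t))` with shared `kon`,
#' `koff`, `Bmax`.
#'
#' @param ts A raw `trace_set` from [simulate_tracer_plate()] (association
#'   mode) with >= 3 tracer concentrations.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `fit_result` with `kon`, `koff`, `KD`, `Bmax`.
#' @export
fit_association_global <- function(ts, maxiter = 60) {
  stopifnot(inherits(ts, "trace_set"))
  .fit_tracer_engine(ts, function(t, L, kon, koff) {
    mono_association_trace(t, L, kon, koff, Bmax = 1, y0 = 0)
  }, maxiter = maxiter)
}

#' Global association-then-dissociation fit across tracer concentrations
#'
#' Fits chase-experiment traces (association up to `t_chase`, exponential
#' dissociation after) with shared `kon`, `koff`, `Bmax` across phases and
#' concentrations.
#'
#' @inheritParams fit_association_global
#' @param t_chase Chase time \[s\]; defaults to the value recorded in the
#'   trace-set metadata.
#' @return A `fit_result` with `kon`, `koff`, `KD`, `Bmax`.
#' @export
fit_assoc_then_dissoc_global <- function(ts, t_chase = NULL, maxiter = 60) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(t_chase)) t_chase <- ts$metadata$t_chase
  if (is.null(t_chase)) stop("'t_chase' not given and absent from metadata", call. = FALSE)
  .fit_tracer_engine(ts, function(t, L, kon, koff) {
    association_then_dissociation_trace(t, t_chase, L, kon, koff, Bmax = 1, y0 = 0)
  }, maxiter = maxiter)
}

# --- dose-response -----------------------------------------------------------

#' One-site competition dose-response fit (IC50)
#'
#' Fits `y = bottom + (top - bottom) / (1 + I/IC50)` (Hill slope fixed at 1,
#' consistent with a 1:1 competitive mechanism) to an ePCA dose-response.
#' `top`/`bottom` are solved linearly; `log10 IC50` is the nonlinear
#' parameter, multi-started over the dose range.
#'
#' @param dr A `dose_response` data.frame (columns `dose_M`,
#'   `response_pct`), e.g. from [simulate_epca()].
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `fit_result` with `IC50`, `top`, `bottom` and a `poor_fit` flag
#'   set when the response is not decreasing in dose beyond noise.
#' @export
fit_dose_response <- function(dr, maxiter = 60) {
  stopifnot(is.data.frame(dr), all(c("dose_M", "response_pct") %in% names(dr)))
  I <- dr$dose_M; y <- dr$response_pct
  nz <- I[I > 0]
  if (length(nz) < 5) stop("invalid data: need >= 6 doses spanning the transition",
                           call. = FALSE)
  basis <- function(theta) {
    w <- 1 / (1 + I / 10^theta[1])
    cbind(1 - w, w)  # bottom, top
  }
  starts <- matrix(seq(log10(min(nz)) - 2, log10(max(nz)) + 2, length.out = 9), ncol = 1)
  best <- .multistart_fit(y, basis, starts,
                          lower = log10(min(nz)) - 6, upper = log10(max(nz)) + 6,
                          tie_dim = NULL, maxiter = maxiter)
  p <- c(best$theta, best$beta)  # logIC50, bottom, top
  window <- abs(p[3] - p[2])
  rsd <- stats::sd(best$resid)
  if (window <= max(3 * rsd, 1e-9 * max(abs(y), 1))) {
    cond <- structure(
      class = c("kinbind_nonconvergence", "error", "condition"),
      list(message = "dose-response window indistinguishable from noise (flat curve)",
           call = sys.call(-1),
           diagnostics = list(window = window, resid_sd = rsd)))
    stop(cond)
  }
  full_model <- function(pp) drop(basis(pp[1]) %*% pp[2:3])
  cv <- .fit_covariance(full_model, p, y)
  s <- .cov_se(cv)
  se <- if (is.null(s)) rep(NA_real_, 3) else s$se
  sei <- if (is.null(s)) rep(NA_real_, 3) else s$se_ill
  params <- rbind(.rate_param_row("IC50", p[1], se[1], sei[1]),
                  .linear_param_row("bottom", p[2], se[2]),
                  .linear_param_row("top", p[3], se[3]))
  # monotonicity check: percent tracer binding should decrease with dose
  ok <- length(nz) > 2
  rho <- suppressWarnings(stats::cor(I[I > 0], y[I > 0], method = "spearman"))
  poor <- ok && is.finite(rho) && rho > 0
  new_fit_result(params, best$sse, length(y), best$n_starts,
                 extra = list(poor_fit = poor))
}

#' Cheng-Prusoff conversion of a competitive IC50 to an affinity
#'
#' `KD_app = IC50 / (1 + L/KD1)` for a competitive one-site mechanism, where
#' `L` and `KD1` are the tracer concentration and affinity.
#'
#' @param IC50 Fitted half-maximal inhibitory concentration \[M\].
#' @param L Tracer concentration \[M\].
#' @param KD1 Tracer equilibrium dissociation constant \[M\].
#' @return Apparent compound dissociation constant \[M\].
#' @export
cheng_prusoff <- function(IC50, L, KD1) {
  check_finite_scalar(IC50, "IC50", min = 0, strict = TRUE)
  check_finite_scalar(L, "L", min = 0, strict = FALSE)
  check_finite_scalar(KD1, "KD1", min = 0, strict = TRUE)
  IC50 / (1 + L / KD1)
}
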