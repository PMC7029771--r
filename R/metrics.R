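#' Coefficient of variation (percent)
#'
#' `CV [%] = SD/mean * 100` with the sample SD (n - 1 denominator).
#'
#' @param values Numeric vector (>= 2 finite values, nonzero mean).
#' @return CV in percent.
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
#' @export
cv_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need >= 2 finite values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Relative error of a mean estimate (percent, signed)
#'
#' `relative error [%] = (input - mean(estimates)) / input * 100`; positive
#' when the estimates underestimate the input value.
#'
#' @param input_value True (input) value, nonzero.
#' @param estimates Numeric vector of estimates.
#' @return Signed percent error.
#' @export
relative_error_percent <- function(input_value, estimates) {
  check_finite_scalar(input_value, "input_value")
  if (input_value == 0) stop("relative error undefined: input value is zero",
                             call. = FALSE)
  100 * (input_value - mean(estimates[is.finite(estimates)])) / input_value
}

#' Z'-factor of an assay window
#'
#' `Z' = 1 - 3 (SDp + SDn) / |mean_p - mean_n|` from positive- and
#' negative-control values. 1 is a perfect assay; the result is symmetric in
#' the labelling of the two groups.
#'
#' @param pos_values,neg_values Control measurements (>= 2 each).
#' @return Z'-factor (<= 1).
#' @examples
#' zprime(rnorm(10, 100, 5), rnorm(10, 0, 5))
#' @export
zprime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2) {
    stop("need >= 2 values per control group", call. = FALSE)
  }
  dm <- abs(mean(pos_values) - mean(neg_values))
  if (dm == 0) stop("Z' undefined: control means are equal", call. = FALSE)
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / dm
}

#' Bland-Altman analysis on log10-transformed pairs
#'
#' Method-comparison statistics on paired positive values: differences
#' `log10(x) - log10(y)`, their mean and SD, and the 95% limits of agreement
#' `mean +/- 1.96 SD`.
#'
#' @param x_values,y_values Paired positive values from the two methods.
#' @return A list with `mean_log_diff`, `sd_log_diff`, `loa_lower`,
#'   `loa_upper`, and the per-pair `differences`.
#' @export
bland_altman_log10 <- function(x_values, y_values) {
  if (length(x_values) != length(y_values)) {
    stop("'x_values' and 'y_values' must be paired", call. = FALSE)
  }
  if (any(x_values <= 0) || any(y_values <= 0)) {
    stop("Bland-Altman on log10 scale requires positive values", call. = FALSE)
  }
  d <- log10(x_values) - log10(y_values)
  m <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(mean_log_diff = m, sd_log_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       differences = d)
}

# longest run of same-sign residuals; systematic model misfit leaves long
# signed runs, random noise does not
longest_signed_run <- function(resid) {
  s <- sign(resid)
  s <- s[s != 0]
  if (length(s) == 0) return(0L)
  r <- rle(s)
  max(r$lengths)
}

#' Residual-pattern statistic of a fit
#'
#' The longest run of same-sign residuals within any single trace of a fit —
#' a simple detector of systematic misfit: under random noise runs stay
#' short, while wrong inputs or a wrong mechanism leave long signed
#' stretches.
#'
#' @param fit A `fit_result` carrying residuals.
#' @return Integer: maximum same-sign run length over traces.
#' @export
residual_run_statistic <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(fit$residuals)) stop("fit carries no residuals", call. = FALSE)
  max(vapply(split(fit$residuals$resid, fit$residuals$trace_id),
             longest_signed_run, integer(1)))
}

#' Monte Carlo precision/accuracy summary
#'
#' Summarises replicate fit results against the true generating parameters:
#' per parameter the mean, SD, CV%, signed relative error % of the mean,
#' median and MAD (robust companions for heavy-tailed drifting estimates),
#' plus bookkeeping of non-converged and ill-determined replicates. Moments
#' are computed over converged replicates; a second set of columns
#' (`*_excl_ill`) excludes ill-determined replicates as well.
#'
#' @param fit_results List of `fit_result` objects (or `NULL` / condition
#'   entries for failed replicates).
#' @param true_params Named list/vector of true values; summarised for every
#'   name present in the fit estimates (e.g. `k3`, `k4`, `KD2`).
#' @return A data.frame, one row per parameter.
#' @export
summarize_mc <- function(fit_results, true_params) {
  ok <- vapply(fit_results, function(x) inherits(x, "fit_result") && isTRUE(x$converged),
               logical(1))
  n_total <- length(fit_results)
  n_converged <- sum(ok)
  if (n_converged < 1) stop("no converged fits to summarise", call. = FALSE)
  fits <- fit_results[ok]
  pars <- names(true_params)
  rows <- lapply(pars, function(p) {
    est <- vapply(fits, function(f) unname(f$estimates[p]), numeric(1))
    ill <- vapply(fits, function(f) isTRUE(f$ill_determined[p]), logical(1))
    keep <- is.finite(est)
    est <- est[keep]; ill <- ill[keep]
    truth <- as.numeric(true_params[[p]])
    stat <- function(v) {
      if (length(v) < 1) return(c(mean = NA, sd = NA, cv = NA, re = NA))
      c(mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        cv = if (length(v) > 1 && mean(v) != 0) 100 * stats::sd(v) / mean(v) else NA,
        re = 100 * (truth - mean(v)) / truth)
    }
    s_all <- stat(est)
    s_ok <- stat(est[!ill])
    data.frame(parameter = p, true_value = truth,
               n_total = n_total, n_converged = n_converged,
               n_ill_determined = sum(ill),
               mean = s_all[["mean"]], sd = s_all[["sd"]],
               cv_pct = s_all[["cv"]], rel_err_pct = s_all[["re"]],
               median = stats::median(est), mad = stats::mad(est),
               mean_excl_ill = s_ok[["mean"]], cv_pct_excl_ill = s_ok[["cv"]],
               rel_err_pct_excl_ill = s_ok[["re"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
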