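#' Tracer specification
#'
#' Describes the labelled probe ("tracer") of a competition binding assay:
#' its free concentration and its 1:1 binding rate constants against the
#' target. All quantities are strict SI (molar, seconds).
#'
#' @param L Free tracer concentration \[M\] (held constant; no depletion).
#' @param k1 Tracer association rate constant \[M^-1 s^-1\].
#' @param k2 Tracer dissociation rate constant \[s^-1\].
#'
#' @return An object of class `tracer_spec` with fields `L`, `k1`, `k2` and
#'   the derived equilibrium dissociation constant `KD1 = k2/k1`.
#' @examples
#' tr <- tracer_spec(L = 12.5e-9, k1 = 2.56e6, k2 = 1.67e-3)
#' tr$KD1
#' @export
tracer_spec <- function(L, k1, k2) {
  check_finite_scalar(L, "L", min = 0, strict = FALSE)
  check_finite_scalar(k1, "k1", min = 0, strict = TRUE)
  check_finite_scalar(k2, "k2", min = 0, strict = TRUE)
  structure(list(L = L, k1 = k1, k2 = k2, KD1 = k2 / k1),
            class = "tracer_spec")
}

#' Unlabelled compound specification
#'
#' Describes the unlabelled test compound competing with the tracer:
#' rate constants, binding mechanism and (for induced fit) isomerisation
#' rates of the receptor:compound complex.
#'
#' @param k3 Compound association rate constant \[M^-1 s^-1\].
#' @param k4 Compound dissociation rate constant \[s^-1\]. Must be > 0 unless
#'   `mechanism = "irreversible"`, where `k4 = 0` is allowed (and forced).
#' @param mechanism One of `"reversible"` (simple 1:1, default),
#'   `"irreversible"`, `"induced-fit"`.
#' @param k_iso_fwd,k_iso_rev Forward/reverse isomerisation rates \[s^-1\] of
#'   the induced-fit step (RI <-> R'I); ignored for other mechanisms.
#'
#' @return An object of class `compound_spec` with the derived affinity
#'   `KD2 = k4/k3` and residence time `RT = 1/k4` (Inf for irreversible).
#' @examples
#' cp <- compound_spec(k3 = 1e6, k4 = 1e-2)
#' cp$RT  # residence time in seconds
#' @export
compound_spec <- function(k3, k4,
                          mechanism = c("reversible", "irreversible", "induced-fit"),
                          k_iso_fwd = 1e-2, k_iso_rev = 1e-3) {
  mechanism <- match.arg(mechanism)
  check_finite_scalar(k3, "k3", min = 0, strict = TRUE)
  check_finite_scalar(k4, "k4", min = 0, strict = (mechanism != "irreversible"))
  if (mechanism == "irreversible" && k4 != 0) {
    stop("irreversible mechanism requires k4 = 0", call. = FALSE)
  }
  if (mechanism == "induced-fit") {
    check_finite_scalar(k_iso_fwd, "k_iso_fwd", min = 0, strict = FALSE)
    check_finite_scalar(k_iso_rev, "k_iso_rev", min = 0, strict = FALSE)
  }
  structure(list(k3 = k3, k4 = k4, mechanism = mechanism,
                 k_iso_fwd = k_iso_fwd, k_iso_rev = k_iso_rev,
                 KD2 = k4 / k3,
                 RT = if (k4 > 0) 1 / k4 else Inf),
            class = "compound_spec")
}

#' Amplitude parameters of the raw-signal model
#'
#' The raw "kinetics of competitive binding" signal is
#' `y(t) = y0 + Bmax * (fractional tracer occupancy)`. The normalised model
#' eliminates both parameters; the raw-signal model needs them.
#'
#' @param Bmax Assay-window amplitude (signal units at full occupancy), > 0.
#' @param y0 Background offset (signal units).
#' @return An object of class `amplitude_params`.
#' @export
amplitude_params <- function(Bmax = 1, y0 = 0) {
  check_finite_scalar(Bmax, "Bmax", min = 0, strict = TRUE)
  check_finite_scalar(y0, "y0")
  structure(list(Bmax = Bmax, y0 = y0), class = "amplitude_params")
}

#' Signal-drift parameters
#'
#' Mono-exponential multiplicative signal decay `exp(-KDrift * t)` applied to
#' the background-subtracted specific signal (models e.g. photobleaching).
#'
#' @param KDrift Decay rate \[s^-1\], >= 0. 0 means no drift.
#' @return An object of class `drift_params`.
#' @export
drift_params <- function(KDrift = 0) {
  check_finite_scalar(KDrift, "KDrift", min = 0, strict = FALSE)
  structure(list(KDrift = KDrift), class = "drift_params")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("Tracer: L = %.4g M, k1 = %.4g M^-1 s^-1, k2 = %.4g s^-1, KD1 = %.4g M\n",
              x$L, x$k1, x$k2, x$KD1))
  invisible(x)
}

#' @export
print.compound_spec <- function(x, ...) {
  cat(sprintf("Compound (%s): k3 = %.4g M^-1 s^-1, k4 = %.4g s^-1, KD2 = %.4g M, RT = %.4g s\n",
              x$mechanism, x$k3, x$k4, x$KD2, x$RT))
  invisible(x)
}

# internal: scalar validation with informative errors
check_finite_scalar <- function(x, name, min = NULL, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (!is.null(min)) {
    if (strict && x <= min) {
      stop(sprintf("'%s' must be > %g (got %g)", name, min, x), call. = FALSE)
    }
    if (!strict && x < min) {
      stop(sprintf("'%s' must be >= %g (got %g)", name, min, x), call. = FALSE)
    }
  }
  invisible(TRUE)
}

as_tracer <- function(x) {
  if (inherits(x, "tracer_spec")) return(x)
  if (is.list(x) && all(c("L", "k1", "k2") %in% names(x))) {
    return(tracer_spec(x$L, x$k1, x$k2))
  }
  stop("expected a tracer_spec (or list with L, k1, k2)", call. = FALSE)
}

as_compound <- function(x) {
  if (inherits(x, "compound_spec")) return(x)
  if (is.list(x) && all(c("k3", "k4") %in% names(x))) {
    return(compound_spec(x$k3, x$k4,
                         mechanism = if (is.null(x$mechanism)) "reversible" else x$mechanism,
                         k_iso_fwd = if (is.null(x$k_iso_fwd)) 1e-2 else x$k_iso_fwd,
                         k_iso_rev = if (is.null(x$k_iso_rev)) 1e-3 else x$k_iso_rev))
  }
  stop("expected a compound_spec (or list with k3, k4)", call. = FALSE)
}
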