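#' Observed eigen-rates of the two-ligand competitive binding system
#'
#' For simultaneous reversible 1:1 binding of a tracer (`k1`, `k2`, free
#' concentration `L`) and an unlabelled compound (`k3`, `k4`, free
#' concentration `I`) to the same site, the linear ODE system has two
#' observed exponential rates `KF >= KS`:
#' \deqn{K_A = k_1 L + k_2, \quad K_B = k_3 I + k_4}
#' \deqn{K_{F,S} = \tfrac12\left[K_A + K_B \pm \sqrt{(K_A-K_B)^2 + 4 k_1 k_3 L I}\right]}
#'
#' @param tracer A [tracer_spec()].
#' @param compound A [compound_spec()] (only `k3`, `k4` are used).
#' @param I Free compound concentration \[M\], >= 0.
#' @return A list of class `eigen_rates` with `KA`, `KB`, `KF`, `KS`,
#'   `Diff = KF - KS` (all s^-1).
#' @examples
#' tr <- tracer_spec(12.5e-9, 2.56e6, 1.67e-3)
#' eigen_rates(tr, compound_spec(1e6, 1e-2), I = 250e-9)
#' @export
eigen_rates <- function(tracer, compound, I) {
  tracer <- as_tracer(tracer); compound <- as_compound(compound)
  check_finite_scalar(I, "I", min = 0, strict = FALSE)
  KA <- tracer$k1 * tracer$L + tracer$k2
  KB <- compound$k3 * I + compound$k4
  disc <- sqrt((KA - KB)^2 + 4 * tracer$k1 * compound$k3 * tracer$L * I)
  KF <- 0.5 * (KA + KB + disc)
  # KS via the product identity KF*KS = k1*L*k4 + k2*k3*I + k2*k4: avoids the
  # cancellation in 0.5*(KA+KB-disc) when disc ~ KA+KB
  prod <- tracer$k1 * tracer$L * compound$k4 + tracer$k2 * compound$k3 * I +
    tracer$k2 * compound$k4
  KS <- if (prod > 0 && KF > 0) prod / KF else 0.5 * (KA + KB - disc)
  structure(list(KA = KA, KB = KB, KF = KF, KS = KS, Diff = KF - KS),
            class = "eigen_rates")
}

# Degenerate-branch handling: when KF ~ KS the closed form has a 0/0; we
# perturb KS slightly instead of using the confluent limit (error < 1e-6).
.regularise_eigen <- function(er) {
  if (er$KF > 0 && abs(er$Diff) < 1e-10 * er$KF) {
    er$KS <- er$KS - 1e-8 * er$KF
    er$Diff <- er$KF - er$KS
  }
  er
}

# Fractional specific tracer binding (Bmax = 1, y0 = 0) at times `t`.
# This is the Motulsky-Mahan tracer-bound trajectory for constant free L, I.
.mm_occupancy <- function(times, tracer, compound, I) {
  if (I == 0) {
    # no competitor: plain tracer association (avoids 0/0 when k4 = 0)
    KA <- tracer$k1 * tracer$L + tracer$k2
    return((tracer$k1 * tracer$L / KA) * (1 - exp(-KA * times)))
  }
  er <- .regularise_eigen(eigen_rates(tracer, compound, I))
  k4 <- compound$k4
  with(er, {
    bracket <- k4 * Diff / (KF * KS) +
      ((k4 - KF) / KF) * exp(-KF * times) -
      ((k4 - KS) / KS) * exp(-KS * times)
    (tracer$k1 * tracer$L / Diff) * bracket
  })
}

#' Raw-signal Motulsky-Mahan competition association trace
#'
#' Specific tracer binding signal over time in the presence of a competing
#' compound at constant free concentrations (no depletion):
#' `y(t) = y0 + Bmax * occupancy(t)`, where the occupancy is the closed-form
#' solution of the two-ligand competitive system. At `I = 0` this reduces to
#' the mono-exponential tracer association curve.
#'
#' @inheritParams eigen_rates
#' @param times Numeric vector of times \[s\], >= 0.
#' @param amplitude An [amplitude_params()] (`Bmax`, `y0`).
#' @return Numeric vector of signals, one per time point.
#' @examples
#' tr <- tracer_spec(12.5e-9, 2.56e6, 1.67e-3)
#' cp <- compound_spec(1e6, 1e-2)
#' specific_binding_trace(seq(0, 400, 10), tr, cp, I = 250e-9)
#' @export
specific_binding_trace <- function(times, tracer, compound, I,
                                   amplitude = amplitude_params()) {
  tracer <- as_tracer(tracer); compound <- as_compound(compound)
  stopifnot(is.numeric(times))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("'times' must be finite and >= 0", call. = FALSE)
  }
  check_finite_scalar(I, "I", min = 0, strict = FALSE)
  amplitude$y0 + amplitude$Bmax * .mm_occupancy(times, tracer, compound, I)
}

#' Normalised Motulsky-Mahan competition trace (percent compound binding)
#'
#' Amplitude-free variant of the competition association model: the specific
#' signal is expressed relative to the vehicle control (tracer only) at the
#' same time point and inverted to percent compound binding,
#' \deqn{\hat y(t>0) = 100\left[1 - \frac{K_A}{\mathrm{Diff}\,(1-e^{-K_A t})}
#'   \left(\frac{k_4 \mathrm{Diff}}{K_F K_S} + \frac{k_4-K_F}{K_F}e^{-K_F t}
#'   - \frac{k_4-K_S}{K_S}e^{-K_S t}\right)\right]}
#' with \eqn{\hat y(0) = 0} by definition (no 0/0 at the origin). Because
#' `Bmax` and `y0` cancel in the ratio, the model is insensitive to any
#' multiplicative signal drift shared with the vehicle control.
#'
#' @inheritParams specific_binding_trace
#' @return Numeric vector, percent compound binding (0-100 for physical
#'   parameters), one per time point.
#' @export
normalized_compound_binding_trace <- function(times, tracer, compound, I) {
  tracer <- as_tracer(tracer); compound <- as_compound(compound)
  stopifnot(is.numeric(times))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("'times' must be finite and >= 0", call. = FALSE)
  }
  check_finite_scalar(I, "I", min = 0, strict = FALSE)
  if (I == 0) return(numeric(length(times)))  # no compound, no compound binding
  er <- .regularise_eigen(eigen_rates(tracer, compound, I))
  k4 <- compound$k4
  out <- numeric(length(times))
  pos <- times > 0
  if (any(pos)) {
    t <- times[pos]
    bracket <- k4 * er$Diff / (er$KF * er$KS) +
      ((k4 - er$KF) / er$KF) * exp(-er$KF * t) -
      ((k4 - er$KS) / er$KS) * exp(-er$KS * t)
    out[pos] <- 100 * (1 - (er$KA / (er$Diff * (1 - exp(-er$KA * t)))) * bracket)
  }
  out
}

#' Percentage of target:tracer equilibrium reached
#'
#' Pseudo-first-order approximation of how far a 1:1 binding reaction has
#' progressed towards its equilibrium plateau at time `t`:
#' \deqn{\%eq = \left(1 - e^{-t (k_{on} L + k_{off})}\right) \times 100.}
#'
#' @param t Time(s) \[s\], >= 0 (vectorised).
#' @param kon Association rate constant \[M^-1 s^-1\].
#' @param L Ligand concentration \[M\].
#' @param koff Dissociation rate constant \[s^-1\].
#' @return Percent of equilibrium reached (0-100).
#' @examples
#' percent_equilibrium(400, kon = 2.56e6, L = 12.5e-9, koff = 1.67e-3)
#' @export
percent_equilibrium <- function(t, kon, L, koff) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0", call. = FALSE)
  }
  check_finite_scalar(kon, "kon", min = 0, strict = TRUE)
  check_finite_scalar(koff, "koff", min = 0, strict = TRUE)
  check_finite_scalar(L, "L", min = 0, strict = FALSE)
  (1 - exp(-t * (kon * L + koff))) * 100
}

#' Pseudo-first-order tracer association trace
#'
#' `B(t) = y0 + Bmax * (L/(L+KD)) * (1 - exp(-(kon*L + koff) * t))` with
#' `KD = koff/kon`; the direct-binding analogue of the competition model at
#' `I = 0`.
#'
#' @param times Times \[s\], >= 0.
#' @param L Tracer concentration \[M\].
#' @param kon,koff Rate constants \[M^-1 s^-1\], \[s^-1\].
#' @param Bmax Signal at full occupancy.
#' @param y0 Background offset.
#' @return Numeric vector of signals.
#' @export
mono_association_trace <- function(times, L, kon, koff, Bmax = 1, y0 = 0) {
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("'times' must be finite and >= 0", call. = FALSE)
  }
  check_finite_scalar(kon, "kon", min = 0, strict = TRUE)
  check_finite_scalar(koff, "koff", min = 0, strict = TRUE)
  check_finite_scalar(L, "L", min = 0, strict = FALSE)
  KD <- koff / kon
  kobs <- kon * L + koff
  y0 + Bmax * (L / (L + KD)) * (1 - exp(-kobs * times))
}

#' Tracer association-then-dissociation trace
#'
#' Piecewise model for a chase experiment: pseudo-first-order association up
#' to `t_chase`, then pure exponential dissociation from the signal reached
#' at the chase point. The chase (excess unlabelled tracer) is assumed to
#' block re-association completely, so the post-chase decay rate is `koff`
#' alone, independent of `L`.
#'
#' @inheritParams mono_association_trace
#' @param t_chase Chase time \[s\], > 0.
#' @return Numeric vector of signals, continuous at `t_chase`.
#' @export
association_then_dissociation_trace <- function(times, t_chase, L, kon, koff,
                                                Bmax = 1, y0 = 0) {
  if (!is.numeric(t_chase) || length(t_chase) != 1L || !is.finite(t_chase) ||
      t_chase <= 0) {
    stop("invalid design: 't_chase' must be a single positive time", call. = FALSE)
  }
  assoc <- mono_association_trace(pmin(times, t_chase), L, kon, koff, Bmax, y0 = 0)
  out <- assoc
  post <- times > t_chase
  if (any(post)) {
    b_chase <- mono_association_trace(t_chase, L, kon, koff, Bmax, y0 = 0)
    out[post] <- b_chase * exp(-koff * (times[post] - t_chase))
  }
  y0 + out
}

#' Apply multiplicative signal drift to a trace
#'
#' Multiplies a (background-subtracted) signal series element-wise by the
#' mono-exponential decay `exp(-KDrift * t)`, modelling binding-independent
#' signal loss such as photobleaching. `KDrift = 0` is the identity.
#'
#' @param series Numeric signal vector.
#' @param times Matching time vector \[s\].
#' @param drift A [drift_params()] object (or a single rate \[s^-1\]).
#' @return The drifted series.
#' @export
apply_signal_drift <- function(series, times, drift) {
  if (is.numeric(drift) && length(drift) == 1L) drift <- drift_params(drift)
  stopifnot(inherits(drift, "drift_params"))
  if (length(series) != length(times)) {
    stop("'series' and 'times' must have the same length", call. = FALSE)
  }
  series * exp(-drift$KDrift * times)
}

#' Equilibrium tracer occupancy under competition
#'
#' Steady-state fractional tracer occupancy of the target in the presence of
#' a competing compound (competitive isotherm):
#' \deqn{occ = \frac{L/K_{D1}}{1 + L/K_{D1} + I/K_{D2}}.}
#' This is the t -> Inf limit of [specific_binding_trace()] (with unit
#' amplitude).
#'
#' @inheritParams eigen_rates
#' @param KD2 Compound equilibrium dissociation constant \[M\].
#' @return Fractional occupancy in (0, 1).
#' @export
equilibrium_competition_occupancy <- function(tracer, KD2, I) {
  tracer <- as_tracer(tracer)
  check_finite_scalar(KD2, "KD2", min = 0, strict = TRUE)
  check_finite_scalar(I, "I", min = 0, strict = FALSE)
  x <- tracer$L / tracer$KD1
  x / (1 + x + I / KD2)
}
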