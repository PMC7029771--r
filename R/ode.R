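#' Mass-action ODE trace for a binding mechanism
#'
#' Numerically integrates the mass-action rate equations of tracer/compound
#' competition for a free target pool, with free ligand concentrations held
#' constant (no depletion), and returns the tracer-bound signal. Supported
#' mechanisms:
#' \describe{
#'   \item{reversible}{simple competitive 1:1 binding of both ligands; this
#'     is the independent numerical oracle for the closed-form
#'     Motulsky-Mahan solution.}
#'   \item{irreversible}{compound binding with `k4 = 0` (absorbing state).}
#'   \item{induced-fit}{compound binds reversibly then the complex
#'     isomerises, `R + I <-> RI <-> R'I`.}
#' }
#'
#' @inheritParams specific_binding_trace
#' @param mechanism Mechanism name; defaults to the compound's own.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @return Numeric vector: `y0 + Bmax * (tracer-bound fraction)` at `times`.
#' @examples
#' tr <- tracer_spec(12.5e-9, 2.56e6, 1.67e-3)
#' cp <- compound_spec(1e6, 1e-2)
#' mechanism_ode_trace(seq(0, 400, 50), tr, cp, I = 250e-9)
#' @export
mechanism_ode_trace <- function(times, tracer, compound, I,
                                amplitude = amplitude_params(),
                                mechanism = NULL,
                                rtol = 1e-10, atol = 1e-12) {
  tracer <- as_tracer(tracer); compound <- as_compound(compound)
  check_finite_scalar(I, "I", min = 0, strict = FALSE)
  if (is.null(mechanism)) mechanism <- compound$mechanism
  mechanism <- match.arg(mechanism, c("reversible", "irreversible", "induced-fit"))
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))

  p <- list(k1 = tracer$k1, k2 = tracer$k2, L = tracer$L,
            k3 = compound$k3, k4 = compound$k4, I = I,
            kf = if (mechanism == "induced-fit") compound$k_iso_fwd else 0,
            kr = if (mechanism == "induced-fit") compound$k_iso_rev else 0)
  # states: RL (tracer-bound), RI (compound-bound), RI2 (isomerised); total
  # target normalised to 1, free target by conservation
  deriv <- function(t, y, p) {
    Rfree <- 1 - y[1] - y[2] - y[3]
    dRL <- p$k1 * p$L * Rfree - p$k2 * y[1]
    dRI <- p$k3 * p$I * Rfree - p$k4 * y[2] - p$kf * y[2] + p$kr * y[3]
    dRI2 <- p$kf * y[2] - p$kr * y[3]
    list(c(dRL, dRI, dRI2))
  }
  tt <- sort(unique(c(0, times)))
  sol <- try(deSolve::lsoda(y = c(RL = 0, RI = 0, RI2 = 0), times = tt,
                            func = deriv, parms = p, rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(tt)) {
    stop(sprintf(paste0("numerical integration failed for mechanism '%s' ",
                        "(k1=%g, k2=%g, L=%g, k3=%g, k4=%g, I=%g)"),
                 mechanism, p$k1, p$k2, p$L, p$k3, p$k4, p$I), call. = FALSE)
  }
  rl <- sol[match(times, tt), "RL"]
  amplitude$y0 + amplitude$Bmax * rl
}
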