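# Configuration parsing and artifact serialisation shared by all commands.
# Quantities in config files may be written with units ("250 nM", "1 hr");
# everything is converted to strict SI (M, s) on load.

.UNIT_FACTORS <- list(
  concentration = c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
                    nM = 1e-9, pM = 1e-12, fM = 1e-15),
  time = c(s = 1, sec = 1, min = 60, h = 3600, hr = 3600),
  rate2 = c("1/s" = 1, "s-1" = 1),
  rate1 = c("1/M/s" = 1, "M-1s-1" = 1)
)

#' Parse a physical quantity with units
#'
#' Accepts a bare number (assumed SI) or a string like `"250 nM"`,
#' `"1 hr"`, `"10 s"`; returns the value in SI units (M or s).
#'
#' @param x Number or string.
#' @param kind `"concentration"` or `"time"`.
#' @param field Field name used in error messages.
#' @return Numeric value in SI units.
#' @export
parse_quantity <- function(x, kind = c("concentration", "time"), field = "value") {
  kind <- match.arg(kind)
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop(sprintf("'%s' must be a number or a '<number> <unit>' string", field),
         call. = FALSE)
  }
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-zµ/1-]*)\\s*$", x))[[1]]
  if (length(m) != 3 || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop(sprintf("'%s': cannot parse quantity '%s'", field, x), call. = FALSE)
  }
  val <- as.numeric(m[2]); unit <- m[3]
  if (unit == "") return(val)
  factors <- .UNIT_FACTORS[[kind]]
  if (!unit %in% names(factors)) {
    stop(sprintf("'%s': unknown %s unit '%s' (expected one of %s)",
                 field, kind, unit, paste(names(factors), collapse = ", ")),
         call. = FALSE)
  }
  val * factors[[unit]]
}

.check_known_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop(sprintf("unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a study configuration (YAML or JSON)
#'
#' Reads a configuration describing tracer, compound(s), assay design, noise
#' and study settings; validates keys (unknown keys are rejected with their
#' name), converts units to SI, and injects documented defaults (400 s
#' observation, 10 s interval, 1% noise, 100 replicates). The defaults
#' actually injected are recorded in the `injected_defaults` attribute.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list of class `study_config` with elements `tracer`
#'   ([tracer_spec()]), `compounds` (list of [compound_spec()]), `design`
#'   ([assay_design()]), `noise` ([noise_model()]), and `study` settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  .check_known_keys(raw, c("tracer", "compound", "compounds", "design",
                           "noise", "perturbation", "study"), "config")
  injected <- character(0)

  tr <- raw$tracer
  if (is.null(tr)) stop("config must define 'tracer'", call. = FALSE)
  .check_known_keys(tr, c("L", "k1", "k2"), "tracer")
  tracer <- tracer_spec(parse_quantity(tr$L, "concentration", "tracer.L"),
                        as.numeric(tr$k1), as.numeric(tr$k2))

  comp_list <- if (!is.null(raw$compounds)) raw$compounds
               else if (!is.null(raw$compound)) list(raw$compound)
               else stop("config must define 'compound' or 'compounds'", call. = FALSE)
  compounds <- lapply(seq_along(comp_list), function(i) {
    cp <- comp_list[[i]]
    .check_known_keys(cp, c("k3", "k4", "mechanism", "k_iso_fwd", "k_iso_rev"),
                      sprintf("compounds[%d]", i))
    compound_spec(as.numeric(cp$k3), as.numeric(cp$k4),
                  mechanism = if (is.null(cp$mechanism)) "reversible" else cp$mechanism,
                  k_iso_fwd = if (is.null(cp$k_iso_fwd)) 1e-2 else as.numeric(cp$k_iso_fwd),
                  k_iso_rev = if (is.null(cp$k_iso_rev)) 1e-3 else as.numeric(cp$k_iso_rev))
  })

  dz <- if (is.null(raw$design)) list() else raw$design
  .check_known_keys(dz, c("observation_time", "interval", "dose_series",
                          "control_replicates", "include_t0"), "design")
  if (is.null(dz$observation_time)) injected <- c(injected, "design.observation_time=400 s")
  if (is.null(dz$interval)) injected <- c(injected, "design.interval=10 s")
  ot <- if (is.null(dz$observation_time)) 400 else parse_quantity(dz$observation_time, "time", "design.observation_time")
  iv <- if (is.null(dz$interval)) 10 else parse_quantity(dz$interval, "time", "design.interval")
  ds <- if (is.null(dz$dose_series)) {
    injected <- c(injected, "design.dose_series=default")
    c(0, 2.5e-9, 25e-9, 250e-9, 2500e-9)
  } else {
    vapply(dz$dose_series, parse_quantity, numeric(1),
           kind = "concentration", field = "design.dose_series")
  }
  design <- assay_design(ot, iv, ds,
                         control_replicates = if (is.null(dz$control_replicates)) 3
                                              else as.integer(dz$control_replicates),
                         include_t0 = isTRUE(dz$include_t0))

  nz <- if (is.null(raw$noise)) list() else raw$noise
  .check_known_keys(nz, c("sd_fraction", "seed"), "noise")
  if (is.null(nz$sd_fraction)) injected <- c(injected, "noise.sd_fraction=0.01")
  noise <- noise_model(if (is.null(nz$sd_fraction)) 0.01 else as.numeric(nz$sd_fraction),
                       seed = if (is.null(nz$seed)) NULL else as.integer(nz$seed))

  pert <- NULL
  if (!is.null(raw$perturbation)) {
    pz <- raw$perturbation
    .check_known_keys(pz, c("kind", "factor", "target_dose_index"), "perturbation")
    pert <- perturbation_spec(pz$kind, as.numeric(pz$factor),
                              target_dose_index = pz$target_dose_index)
  }

  st <- if (is.null(raw$study)) list() else raw$study
  .check_known_keys(st, c("kind", "n_replicates", "seed"), "study")
  if (is.null(st$n_replicates)) injected <- c(injected, "study.n_replicates=100")
  study <- list(kind = st$kind,
                n_replicates = if (is.null(st$n_replicates)) 100L else as.integer(st$n_replicates),
                seed = if (is.null(st$seed)) 1L else as.integer(st$seed))

  structure(list(tracer = tracer, compounds = compounds, design = design,
                 noise = noise, perturbation = pert, study = study),
            class = "study_config", injected_defaults = injected)
}

#' Write a trace set to long-format CSV (with JSON metadata sidecar)
#'
#' Columns: `trace_id, role, dose_M, time_s, signal, state`. Values survive
#' a write/read round trip losslessly (full double precision). Generating
#' parameters and the seed are written to `<path>.json`.
#'
#' @param ts A `trace_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  d <- ts$data
  d$state <- ts$state
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  meta <- ts$metadata
  meta$package_version <- as.character(utils::packageVersion("kinbind"))
  jsonlite::write_json(.meta_serialisable(meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.meta_serialisable <- function(x) {
  if (is.list(x)) lapply(unclass(x), .meta_serialisable) else x
}

#' Read a trace set from long-format CSV
#'
#' Inverse of [write_traces()]. Tolerates CRLF line endings and scientific
#' notation; rejects files with missing columns, mixed `state` values or
#' duplicated `(trace_id, time_s)` pairs, naming the offending row.
#'
#' @param path CSV path; `<path>.json` metadata is restored when present.
#' @return A `trace_set`.
#' @export
read_traces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "role", "dose_M", "time_s", "signal", "state")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop(sprintf("parse error: missing column%s %s",
                 if (length(missing_cols) > 1) "s" else "",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  states <- unique(d$state)
  if (length(states) != 1 || !states %in% c("raw", "normalised")) {
    stop("parse error: 'state' must be a single value, raw or normalised",
         call. = FALSE)
  }
  dup <- duplicated(d[, c("trace_id", "time_s")])
  if (any(dup)) {
    stop(sprintf("parse error: duplicated (trace_id, time) at row %d",
                 which(dup)[1] + 1L), call. = FALSE)
  }
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$tracer_nominal)) {
      meta$tracer_nominal <- tracer_spec(meta$tracer_nominal$L,
                                         meta$tracer_nominal$k1,
                                         meta$tracer_nominal$k2)
    }
  }
  new_trace_set(d[, need[1:5]], state = states, metadata = meta)
}

#' Serialise a fit result to JSON
#'
#' Writes estimates, standard errors, confidence intervals,
#' ill-determinedness flags, SSE and start diagnostics.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(package_version = as.character(utils::packageVersion("kinbind")),
                  converged = fit$converged, sse = fit$sse,
                  n_points = fit$n_points, n_starts_used = fit$n_starts_used,
                  parameters = fit$parameters)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
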